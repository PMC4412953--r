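# mut_classify: HX4D motif search, torsion-based secondary structure,
# structural location classes and the electrostatic/stability flag rules with
# proposed functional effects.

#' Find HX4D catalytic motifs
#'
#' Scans for His at position `i` with Asp at `i + 5` (His-X-X-X-X-Asp), the
#' catalytic motif of glycerolipid acyltransferases.
#'
#' @param seq A [SequenceRecord] (or string).
#' @return `data.frame` with columns `his` and `asp` (biological numbering),
#'   one row per hit; zero rows when absent.
#' @export
#' @examples
#' findHX4D("AHAAAADAA")  # His at 2, Asp at 7
findHX4D <- function(seq) {
  rec <- .asSequenceRecord(seq)
  ch <- .seqChars(rec)
  n <- length(ch)
  hits <- if (n >= 6) which(ch[1:(n - 5)] == "H" & ch[6:n] == "D")
  else integer(0)
  data.frame(his = hits + rec@offset, asp = hits + 5L + rec@offset)
}

#' Torsion-window secondary-structure assignment
#'
#' Backbone phi/psi torsions are computed from N, CA, C atoms. A residue is
#' helical when phi in [-100, -30] and psi in [-80, -5] degrees, in runs of
#' at least 4; strand when phi in [-180, -40] and psi in [60, 180], in runs
#' of at least 3; otherwise coil. Residues with undefined torsions (chain
#' termini, missing backbone atoms) are coil; missing backbone atoms draw a
#' warning.
#'
#' @param structure A [PdbStructure].
#' @return Named character vector of labels (`"H"`, `"E"`, `"C"`), keyed by
#'   residue key.
#' @export
assignSecondaryStructure <- function(structure) {
  r <- residueTable(structure)
  a <- structure@atoms
  akeys <- .resKey(a)
  getAtom <- function(key, name) {
    rows <- which(akeys == key & a$elety == name)
    if (length(rows)) as.numeric(a[rows[1], c("x", "y", "z")]) else NULL
  }
  n <- nrow(r)
  phi <- psi <- rep(NA_real_, n)
  missingBackbone <- FALSE
  bk <- lapply(r$key, function(k)
    list(N = getAtom(k, "N"), CA = getAtom(k, "CA"), C = getAtom(k, "C")))
  for (i in seq_len(n)) {
    if (any(vapply(bk[[i]], is.null, logical(1)))) {
      missingBackbone <- TRUE
      next
    }
    sameChainPrev <- i > 1 && r$chain[i - 1] == r$chain[i]
    sameChainNext <- i < n && r$chain[i + 1] == r$chain[i]
    if (sameChainPrev && !is.null(bk[[i - 1]]$C))
      phi[i] <- .dihedral(bk[[i - 1]]$C, bk[[i]]$N, bk[[i]]$CA, bk[[i]]$C)
    if (sameChainNext && !is.null(bk[[i + 1]]$N))
      psi[i] <- .dihedral(bk[[i]]$N, bk[[i]]$CA, bk[[i]]$C, bk[[i + 1]]$N)
  }
  if (missingBackbone)
    warning("residue(s) with missing backbone atoms labelled C")
  isH <- !is.na(phi) & !is.na(psi) & phi >= -100 & phi <= -30 &
    psi >= -80 & psi <= -5
  isE <- !is.na(phi) & !is.na(psi) & phi >= -180 & phi <= -40 &
    psi >= 60 & psi <= 180
  ss <- rep("C", n)
  segH <- .runsOf(isH)
  if (nrow(segH)) for (s in seq_len(nrow(segH)))
    if (segH[s, 2] - segH[s, 1] + 1L >= 4L)
      ss[segH[s, 1]:segH[s, 2]] <- "H"
  segE <- .runsOf(isE)
  if (nrow(segE)) for (s in seq_len(nrow(segE)))
    if (segE[s, 2] - segE[s, 1] + 1L >= 3L)
      ss[segE[s, 1]:segE[s, 2]] <- "E"
  stats::setNames(ss, r$key)
}

#' Classify the structural location of a mutated residue
#'
#' Assigns one of `"catalytic"`, `"cleft"`, `"buried"`, `"surface"` with the
#' precedence catalytic > cleft > buried > surface. A surface residue is
#' non-buried; it carries a `"distal"` qualifier (attribute) when it is
#' neither a patch member nor within `patchDistance` of a patch centroid.
#'
#' @param position Residue position (author numbering).
#' @param catalytic Integer vector of catalytic residue positions.
#' @param cleft Character vector of cleft residue keys, or integer positions.
#' @param profile An [AccessibilityProfile].
#' @param patches A [PatchSet] (may be empty).
#' @param structure The [PdbStructure]; needed to resolve the position.
#' @param chain Chain to interpret `position` in (default first chain).
#' @param patchDistance Distance (A) from a patch centroid within which a
#'   non-buried residue counts as membrane-associated surface (default 10).
#' @return Character location; attribute `"qualifier"` may hold `"distal"`.
#' @export
classifyLocation <- function(position, catalytic, cleft, profile, patches,
                             structure, chain = NULL, patchDistance = 10) {
  r <- residueTable(structure)
  if (is.null(chain)) chain <- r$chain[1]
  row <- which(r$chain == chain & r$resno == position)
  if (!length(row))
    stop("position ", position, " not present in structure chain ", chain)
  key <- r$key[row[1]]
  cleftKeys <- if (is.character(cleft)) cleft
  else r$key[r$chain == chain & r$resno %in% as.integer(cleft)]
  if (position %in% catalytic) return("catalytic")
  if (key %in% cleftKeys) return("cleft")
  buried <- isBuried(profile)
  if (isTRUE(buried[key])) return("buried")
  # surface: in a patch or near a patch centroid, else distal surface
  inPatch <- any(vapply(patchMembers(patches), function(p) key %in% p,
                        logical(1)))
  near <- FALSE
  cents <- patchCentroids(patches)
  if (!inPatch && nrow(cents)) {
    atoms <- structure@atoms
    sel <- .resKey(atoms) == key & toupper(atoms$element) != "H"
    xyz <- as.matrix(atoms[sel, c("x", "y", "z")])
    d <- sqrt(outer(rowSums(xyz^2), rowSums(cents^2), "+") -
                2 * xyz %*% t(cents))
    near <- min(d) <= patchDistance
  }
  out <- "surface"
  if (!inPatch && !near) attr(out, "qualifier") <- "distal"
  out
}

#' Electrostatic and stability flags for a missense mutation
#'
#' The electrostatic flag is set when the charge class of the reference and
#' alternate residues differ (classes: negative D/E, positive K/R, histidine
#' H, neutral otherwise). The stability flag is set when any of these rules
#' fires:
#' \itemize{
#'   \item (a) the alternate residue is Pro (backbone amide lost);
#'   \item (b) the alternate is Gly and the site is in the cleft or buried;
#'   \item (c) the reference residue is Gly (backbone flexibility lost);
#'   \item (d) the site is buried and the charge class changes;
#'   \item (e) the site is in the cleft or buried and the side-chain volume
#'     change reaches `dvThreshold` (Zamyatnin volumes);
#'   \item (f) the site is on the surface, the reference is hydrophobic
#'     (A,V,L,I,M,F,W,C) and the alternate polar (S,T,N,Q,Y,H).
#' }
#'
#' @param ref,alt One-letter reference/alternate residues.
#' @param location Location class from [classifyLocation()] (or a printed
#'   location label; `"catalytic site"` etc. are normalized).
#' @param scheme Charge scheme, see [chargeScheme()].
#' @param volumes Residue volume table (A^3), default [residueVolumes()].
#' @param dvThreshold Volume-change threshold in A^3 (default 20).
#' @param ss Optional secondary-structure label at the site (`"H"`, `"E"`,
#'   `"C"`); mentioned in the rule trace when a Pro substitution hits a
#'   helix or strand.
#' @return List with logical `electrostatic`, `stability` and a character
#'   vector `rules` naming every rule that fired.
#' @export
#' @examples
#' effectFlags("H", "Q", "catalytic")$electrostatic  # TRUE
#' effectFlags("T", "P", "buried")$stability         # TRUE
effectFlags <- function(ref, alt, location, scheme = chargeScheme(),
                        volumes = residueVolumes(), dvThreshold = 20,
                        ss = NULL) {
  loc <- .normalizeLocation(location)
  cls <- scheme$classes
  chargeChange <- !identical(unname(cls[ref]), unname(cls[alt]))
  rules <- character(0)
  if (chargeChange)
    rules <- c(rules, sprintf("electrostatic: charge class %s -> %s",
                              cls[ref], cls[alt]))
  stab <- FALSE
  hydroph <- c("A", "V", "L", "I", "M", "F", "W", "C")
  polar <- c("S", "T", "N", "Q", "Y", "H")
  if (alt == "P") {
    stab <- TRUE
    note <- if (!is.null(ss) && ss %in% c("H", "E"))
      sprintf(" in secondary structure (%s)", ss) else ""
    rules <- c(rules, paste0("stability(a): substitution to Pro", note))
  }
  if (alt == "G" && loc %in% c("cleft", "buried")) {
    stab <- TRUE
    rules <- c(rules, "stability(b): substitution to Gly at cleft/buried site")
  }
  if (ref == "G") {
    stab <- TRUE
    rules <- c(rules, "stability(c): substitution of Gly")
  }
  if (loc == "buried" && chargeChange) {
    stab <- TRUE
    rules <- c(rules, "stability(d): charge-class change at buried site")
  }
  dv <- abs(volumes[alt] - volumes[ref])
  if (loc %in% c("cleft", "buried") && !is.na(dv) && dv >= dvThreshold) {
    stab <- TRUE
    rules <- c(rules, sprintf(
      "stability(e): side-chain volume change %.1f A^3 at cleft/buried site", dv))
  }
  if (loc == "surface" && ref %in% hydroph && alt %in% polar) {
    stab <- TRUE
    rules <- c(rules, "stability(f): hydrophobic-to-polar at surface site")
  }
  list(electrostatic = chargeChange, stability = stab, rules = rules)
}

.normalizeLocation <- function(location) {
  l <- tolower(trimws(location))
  if (grepl("^catalytic", l)) return("catalytic")
  if (grepl("^cleft", l)) return("cleft")
  if (grepl("^buried", l)) return("buried")
  if (grepl("^surface", l)) return("surface")
  stop("unknown location label: ", location)
}

#' Proposed functional effect of a mutation
#'
#' Deterministic mapping from the structural location class: catalytic ->
#' "Catalytic activity", cleft -> "Substrate binding", surface -> "Membrane
#' association", buried -> "Destabilization".
#'
#' @param location Location class or printed label.
#' @return Character effect label.
#' @export
#' @examples
#' proposeEffect("buried")
proposeEffect <- function(location) {
  switch(.normalizeLocation(location),
         catalytic = "Catalytic activity",
         cleft = "Substrate binding",
         surface = "Membrane association",
         buried = "Destabilization")
}

#' Annotate a table of missense mutations
#'
#' Applies [effectFlags()] and [proposeEffect()] to every row of a mutation
#' table that carries a `location` column (printed labels accepted), e.g. the
#' packaged mutation fixture or the output of a structural location pass.
#'
#' @param mutations `data.frame` with columns `ref`, `position`, `alt`,
#'   `location` (see [readMutationTable()]).
#' @param ss Optional character vector of secondary-structure labels aligned
#'   with the table rows (one of `"H"`, `"E"`, `"C"` per mutation).
#' @param dvThreshold Volume-change threshold, see [effectFlags()].
#' @return The input with added columns `electrostatic`, `stability`
#'   (logical), `effect` and `rules` (collapsed rule trace).
#' @export
annotateMutations <- function(mutations, ss = NULL, dvThreshold = 20) {
  n <- nrow(mutations)
  el <- st <- logical(n)
  eff <- rl <- character(n)
  for (i in seq_len(n)) {
    f <- effectFlags(mutations$ref[i], mutations$alt[i],
                     mutations$location[i], dvThreshold = dvThreshold,
                     ss = if (!is.null(ss)) unname(ss[i]) else NULL)
    el[i] <- f$electrostatic
    st[i] <- f$stability
    eff[i] <- proposeEffect(mutations$location[i])
    rl[i] <- paste(f$rules, collapse = "; ")
  }
  out <- mutations
  out$electrostatic <- el
  out$stability <- st
  out$effect <- eff
  out$rules <- rl
  out
}
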