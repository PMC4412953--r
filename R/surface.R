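# surface_core: Shrake-Rupley solvent accessibility, burial flags, residue
# contacts and the connected buried core.

#' Shrake-Rupley solvent-accessible surface area
#'
#' Point-sampling SASA over the heavy (non-hydrogen) polymer atoms. Each atom
#' is expanded by the probe radius and sampled with a deterministic Fibonacci
#' lattice; a point is accessible when it lies outside every neighbouring
#' expanded sphere. To make the areas invariant under rigid motion of the
#' input (rather than invariant only up to the lattice quantum), coordinates
#' are internally rotated into a canonical principal-axis frame before
#' sampling.
#'
#' @param structure A [PdbStructure].
#' @param probeRadius Solvent probe radius in A (default 1.4).
#' @param nSpherePoints Sampling points per atom (default 960).
#' @param radii Named van der Waals radius table by element; defaults to
#'   [vdwRadius()]'s table.
#' @param onUnknown Behaviour for elements without a tabulated radius, see
#'   [vdwRadius()].
#' @return Numeric vector of per-atom areas (A^2) for the heavy polymer atoms,
#'   named by atom row index in `atomTable(structure)`; hydrogens are skipped.
#' @export
#' @examples
#' h <- buildHelix("AAAAAAAAAAAA")
#' sum(computeSasa(h))
computeSasa <- function(structure, probeRadius = 1.4, nSpherePoints = 960L,
                        radii = NULL, onUnknown = c("warn", "default", "error")) {
  onUnknown <- match.arg(onUnknown)
  a <- structure@atoms
  heavy <- which(toupper(a$element) != "H")
  if (!length(heavy)) stop("structure has no heavy atoms")
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  if (is.null(radii)) {
    r <- vdwRadius(a$element[heavy], onUnknown = onUnknown)
  } else {
    r <- radii[toupper(a$element[heavy])]
    if (any(is.na(r))) {
      if (onUnknown == "error")
        stop("element(s) missing from radius table")
      if (onUnknown == "warn") warning("element(s) missing from radius table; using 1.7")
      r[is.na(r)] <- 1.70
    }
    r <- unname(r)
  }
  rexp <- r + probeRadius
  n <- length(heavy)
  xyz <- .canonicalCoords(xyz)
  unit <- fibonacciSphere(nSpherePoints)

  # neighbour lists from squared distances (block if large)
  area <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    ri <- rexp[i]
    nb <- which(d2[i, ] < (ri + rexp)^2 & seq_len(n) != i)
    pts <- unit * ri
    pts <- sweep(pts, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nSpherePoints)
    for (j in nb) {
      dj <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & (dj > rexp[j]^2)
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * ri^2 * sum(acc) / nSpherePoints
  }
  stats::setNames(area, heavy)
}

#' Per-residue SASA from per-atom areas
#'
#' @param structure A [PdbStructure].
#' @param atomAreas Output of [computeSasa()] on the same structure.
#' @return Named numeric vector of residue SASA (A^2), keyed by residue key.
#' @export
residueSasa <- function(structure, atomAreas) {
  a <- structure@atoms
  idx <- as.integer(names(atomAreas))
  keys <- .resKey(a[idx, , drop = FALSE])
  sums <- tapply(atomAreas, keys, sum)
  r <- residueTable(structure)
  out <- stats::setNames(rep(0, nrow(r)), r$key)
  out[names(sums)] <- as.numeric(sums)
  out
}

#' Relative accessibility and burial flags
#'
#' Normalizes residue SASA by a per-residue-type maximum and flags residues
#' whose relative accessibility is strictly below the threshold as buried.
#'
#' @param structure A [PdbStructure].
#' @param atomAreas Output of [computeSasa()] on the same structure.
#' @param maxAsa Named max-ASA table (A^2); defaults to [maxAsaTable()].
#'   Residues of type `"X"` get the mean table value.
#' @param threshold Burial threshold (default 0.1, strict `<`).
#' @return An [AccessibilityProfile].
#' @export
relativeAccessibility <- function(structure, atomAreas, maxAsa = maxAsaTable(),
                                  threshold = 0.1) {
  r <- residueTable(structure)
  rs <- residueSasa(structure, atomAreas)
  mx <- maxAsa[r$aa]
  unknown <- is.na(mx)
  if (any(unknown & r$aa != "X"))
    stop("residue type(s) absent from max-ASA table: ",
         paste(unique(r$aa[unknown & r$aa != "X"]), collapse = ", "))
  mx[unknown] <- mean(maxAsa)
  rel <- as.numeric(rs[r$key] / mx)
  res <- data.frame(key = r$key, chain = r$chain, resno = r$resno,
                    icode = r$icode, aa = r$aa, sasa = as.numeric(rs[r$key]),
                    relAcc = rel, buried = rel < threshold,
                    stringsAsFactors = FALSE)
  new("AccessibilityProfile", residues = res, threshold = threshold)
}

#' Full accessibility profile in one call
#'
#' Convenience wrapper running [computeSasa()] then
#' [relativeAccessibility()].
#'
#' @inheritParams computeSasa
#' @inheritParams relativeAccessibility
#' @return An [AccessibilityProfile].
#' @export
accessibilityProfile <- function(structure, probeRadius = 1.4,
                                 nSpherePoints = 960L,
                                 maxAsa = maxAsaTable(), threshold = 0.1) {
  relativeAccessibility(
    structure,
    computeSasa(structure, probeRadius = probeRadius,
                nSpherePoints = nSpherePoints),
    maxAsa = maxAsa, threshold = threshold)
}

#' Residue contact graph
#'
#' Two residues are in contact when their minimum heavy-atom distance is at
#' most `cutoff`. Sequence neighbours are included.
#'
#' @param structure A [PdbStructure].
#' @param cutoff Distance cutoff in A (default 4.5, must be > 0).
#' @return A [ContactGraph].
#' @export
residueContacts <- function(structure, cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  a <- structure@atoms
  heavy <- toupper(a$element) != "H"
  a <- a[heavy, , drop = FALSE]
  if (!nrow(a)) stop("structure has no heavy atoms")
  keys <- .resKey(a)
  ukeys <- unique(keys)
  ridx <- match(keys, ukeys)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  inCut <- d <= cutoff
  pairs <- which(inCut & upper.tri(inCut), arr.ind = TRUE)
  if (nrow(pairs)) {
    ri <- ridx[pairs[, 1]]; rj <- ridx[pairs[, 2]]
    keep <- ri != rj
    pr <- unique(cbind(pmin(ri[keep], rj[keep]), pmax(ri[keep], rj[keep])))
    pm <- cbind(ukeys[pr[, 1]], ukeys[pr[, 2]])
  } else {
    pm <- matrix(character(0), 0, 2)
  }
  new("ContactGraph", pairs = pm, cutoff = cutoff)
}

#' Structural core: connected components of buried residues
#'
#' Buried residues that are in contact with one another form the protein
#' core: the connected components of the contact graph induced on the buried
#' set. Isolated buried residues (components of size 1) are discarded.
#'
#' @param profile An [AccessibilityProfile].
#' @param contacts A [ContactGraph] from the same structure.
#' @return A [CoreSet]; components are sorted by decreasing size.
#' @export
structuralCore <- function(profile, contacts) {
  buried <- names(which(isBuried(profile)))
  if (!length(buried))
    return(new("CoreSet", components = list(), buried = character(0)))
  p <- contactPairs(contacts)
  keep <- p[, 1] %in% buried & p[, 2] %in% buried
  p <- p[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = p[, 1], to = p[, 2], stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = buried))
  cmp <- igraph::components(g)
  comp <- split(names(cmp$membership), cmp$membership)
  comp <- comp[lengths(comp) >= 2]
  comp <- lapply(comp, function(x) sort(x))
  comp <- comp[order(-lengths(comp))]
  names(comp) <- NULL
  new("CoreSet", components = comp, buried = buried)
}

#' Hydrophobic composition of the structural core
#'
#' @param core A [CoreSet].
#' @param structure The [PdbStructure] it was computed on.
#' @param hydrophobic Character vector of one-letter codes counted as
#'   hydrophobic; defaults to [hydrophobicSet()].
#' @return List with `total` residues in the core, `hydrophobic` count over
#'   all components, and `perComponent` data.frame (`size`, `hydrophobic`).
#' @export
coreHydrophobicStats <- function(core, structure,
                                 hydrophobic = hydrophobicSet()) {
  r <- residueTable(structure)
  aaOf <- stats::setNames(r$aa, r$key)
  comp <- coreComponents(core)
  per <- data.frame(
    size = lengths(comp),
    hydrophobic = vapply(comp, function(m) sum(aaOf[m] %in% hydrophobic),
                         integer(1)))
  list(total = sum(per$size), hydrophobic = sum(per$hydrophobic),
       perComponent = per)
}
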