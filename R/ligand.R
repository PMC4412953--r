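# ligand_geom: phosphate-spacing statistics of dimeric phospholipids and
# compatibility matching against basic-residue pairs.

#' Phosphate-group spacing of a dimeric phospholipid
#'
#' Distance between the oxygen centroids of the ligand's two phosphate
#' groups (default convention). Alternatives: the minimum O-O distance
#' between the groups, or the P-P distance.
#'
#' @param ligand A [CLLigand] with exactly two phosphate groups.
#' @param mode `"o_centroid"` (default), `"min_oo"` or `"pp"`.
#' @return Spacing in A.
#' @export
phosphateSpacing <- function(ligand, mode = c("o_centroid", "min_oo", "pp")) {
  mode <- match.arg(mode)
  g <- ligand@groups
  if (length(g) != 2)
    stop("ligand ", ligand@id, " has ", length(g),
         " phosphate group(s); exactly 2 required")
  xyz <- as.matrix(ligand@atoms[, c("x", "y", "z")])
  if (mode == "pp")
    return(sqrt(sum((xyz[g[[1]]$P, ] - xyz[g[[2]]$P, ])^2)))
  o1 <- xyz[g[[1]]$O, , drop = FALSE]
  o2 <- xyz[g[[2]]$O, , drop = FALSE]
  if (!nrow(o1) || !nrow(o2))
    stop("phosphate group without oxygen atoms in ", ligand@id)
  if (mode == "o_centroid")
    return(sqrt(sum((colMeans(o1) - colMeans(o2))^2)))
  d2 <- outer(rowSums(o1^2), rowSums(o2^2), "+") - 2 * o1 %*% t(o2)
  sqrt(max(0, min(d2)))
}

#' Aggregate phosphate-spacing statistics
#'
#' Sample mean and (n-1)-denominator standard deviation of per-ligand
#' spacings; with a single ligand the sd is reported as 0.
#'
#' @param ligandList Non-empty list of [CLLigand] objects.
#' @param mode Spacing convention, see [phosphateSpacing()].
#' @return A [SpacingStats].
#' @export
aggregateSpacing <- function(ligandList, mode = "o_centroid") {
  if (!length(ligandList)) stop("empty ligand list")
  sp <- vapply(ligandList, phosphateSpacing, numeric(1), mode = mode)
  s <- if (length(sp) > 1) stats::sd(sp) else 0
  new("SpacingStats", spacings = unname(sp), mean = mean(sp), sd = s,
      n = length(sp))
}

#' Match basic residue pairs to a phosphate-spacing reference
#'
#' Scores every pair of the given basic residues by the minimal distance
#' between their side-chain terminal nitrogens (Nz for Lys, Nh for Arg) and
#' flags the pair compatible when the distance lies within
#' `reference mean +- tolerance`. Residues lacking a side-chain terminal N
#' are skipped with a warning.
#'
#' @param basics Character vector of residue keys (`"A:106"`).
#' @param structure A [PdbStructure].
#' @param reference A [SpacingStats] (e.g. from cardiolipin survey data or
#'   [makeClLigands()]).
#' @param tolerance Compatibility tolerance in A (default 3.0).
#' @return `data.frame` with columns `res1`, `res2`, `distance`,
#'   `compatible`; zero rows when fewer than two usable residues.
#' @export
matchBasicPairs <- function(basics, structure, reference, tolerance = 3.0) {
  a <- structure@atoms
  akeys <- .resKey(a)
  usable <- character(0)
  coords <- list()
  for (k in basics) {
    rows <- a[akeys == k & a$elety %in% c("NZ", "NH1", "NH2"), , drop = FALSE]
    if (!nrow(rows)) {
      warning("residue ", k, " lacks a side-chain terminal N; skipped")
      next
    }
    usable <- c(usable, k)
    coords[[k]] <- as.matrix(rows[, c("x", "y", "z")])
  }
  out <- data.frame(res1 = character(0), res2 = character(0),
                    distance = numeric(0), compatible = logical(0),
                    stringsAsFactors = FALSE)
  if (length(usable) < 2) return(out)
  ref <- spacingMean(reference)
  for (i in seq_len(length(usable) - 1)) for (j in (i + 1):length(usable)) {
    ci <- coords[[usable[i]]]; cj <- coords[[usable[j]]]
    d2 <- outer(rowSums(ci^2), rowSums(cj^2), "+") - 2 * ci %*% t(cj)
    d <- sqrt(max(0, min(d2)))
    out <- rbind(out, data.frame(
      res1 = usable[i], res2 = usable[j], distance = d,
      compatible = abs(d - ref) <= tolerance, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
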