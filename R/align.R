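# access_align: global pairwise alignment with position-specific gap-open
# penalties derived from template solvent accessibility, plus identity and
# core-conservation statistics.

#' Gap-open profile from template accessibility
#'
#' Linear interpolation between `gMax` (fully buried template position) and
#' `gMin` (fully exposed): `open(i) = gMin + (gMax - gMin) * (1 -
#' min(relAcc_i, 1))`. Exposed positions are cheapest to gap, encoding the
#' structural prior that indels fall in loops on the protein surface.
#'
#' @param templateAccessibility An [AccessibilityProfile] of the template
#'   structure, or a plain numeric vector of per-position relative
#'   accessibilities in template sequence order.
#' @param gMax Open penalty at relative accessibility 0 (default 12).
#' @param gMin Open penalty at relative accessibility >= 1 (default 4).
#' @param extend Gap extension penalty (default 1).
#' @return A [GapProfile].
#' @export
#' @examples
#' gapProfile(c(0, 0.5, 1), gMax = 12, gMin = 4)@open  # 12 8 4
gapProfile <- function(templateAccessibility, gMax = 12, gMin = 4,
                       extend = 1) {
  if (!(gMax >= gMin && gMin > extend && extend >= 0))
    stop("parameter ordering violated: need gMax >= gMin > extend >= 0")
  rel <- if (is(templateAccessibility, "AccessibilityProfile"))
    accessibilityTable(templateAccessibility)$relAcc
  else as.numeric(templateAccessibility)
  if (!length(rel)) stop("template accessibility is empty")
  open <- gMin + (gMax - gMin) * (1 - pmin(rel, 1))
  new("GapProfile", open = open, extend = extend, gMax = gMax, gMin = gMin)
}

#' Uniform gap profile
#'
#' Convenience constructor for a position-independent profile (all open
#' penalties equal), under which [alignPair()] reduces to a standard global
#' affine-gap aligner.
#'
#' @param length Template length.
#' @param open Gap-open penalty.
#' @param extend Gap-extension penalty.
#' @return A [GapProfile].
#' @export
uniformGapProfile <- function(length, open = 12, extend = 1) {
  new("GapProfile", open = rep(open, length), extend = extend,
      gMax = open, gMin = open)
}

.substitutionMatrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

.asSequenceRecord <- function(x, id = "seq") {
  if (is(x, "SequenceRecord")) return(x)
  new("SequenceRecord", id = id, seq = toupper(as.character(x)), offset = 0L)
}

#' Global alignment with template-position-specific gap penalties
#'
#' Optimal global affine-gap alignment (Gotoh recursion) in which the cost of
#' opening a gap depends on the template position being gapped: deleting
#' template positions `j1..j2` costs `open(j1) + (L-1) * extend`; inserting
#' target residues between template positions `j` and `j+1` costs
#' `open(j+1) + (L-1) * extend` (the last position's penalty at the template
#' end). Terminal gaps are penalized like internal ones. Traceback ties are
#' broken deterministically, preferring diagonal over a gap in the template
#' over a gap in the target.
#'
#' @param target,template [SequenceRecord] objects (or plain strings).
#' @param profile A [GapProfile] with one open penalty per template position.
#' @param matrix Substitution matrix: a name from Biostrings (default
#'   `"BLOSUM62"`) or a numeric matrix.
#' @return A [PairAlignment].
#' @export
#' @examples
#' a <- alignPair("HEAGAWGHEE", "PAWHEAE",
#'                uniformGapProfile(7, open = 10, extend = 1))
#' alignmentScore(a)
alignPair <- function(target, template, profile, matrix = "BLOSUM62") {
  target <- .asSequenceRecord(target, "target")
  template <- .asSequenceRecord(template, "template")
  sub <- .substitutionMatrix(matrix)
  matName <- if (is.character(matrix)) matrix else "custom"
  tch <- strsplit(target@seq, "")[[1]]
  sch <- strsplit(template@seq, "")[[1]]
  n <- length(tch); m <- length(sch)
  if (length(profile@open) != m)
    stop("gap profile length (", length(profile@open),
         ") must equal template length (", m, ")")
  if (!all(c(tch, sch) %in% rownames(sub)))
    stop("sequence symbol(s) outside the substitution matrix alphabet")
  S <- sub[tch, sch, drop = FALSE]
  open <- profile@open
  ext <- profile@extend
  openIns <- c(open[-1], open[m])  # open penalty for insertions after col j

  NEG <- -1e9
  # state matrices over (i = 0..n, j = 0..m)
  M <- matrix(NEG, n + 1, m + 1)   # column ends in a match/mismatch
  Ix <- matrix(NEG, n + 1, m + 1)  # ends with target residue vs gap
  Iy <- matrix(NEG, n + 1, m + 1)  # ends with template residue vs gap
  M[1, 1] <- 0
  # traceback: 0 diag-from-M-best, per-state predecessors
  tbM <- matrix(0L, n + 1, m + 1)  # 1=M, 2=Ix, 3=Iy predecessor of diag step
  tbX <- matrix(0L, n + 1, m + 1)  # 1=open (from M), 2=extend
  tbY <- matrix(0L, n + 1, m + 1)
  if (n >= 1) {
    Ix[2, 1] <- -open[1]; tbX[2, 1] <- 1L
    if (n >= 2) for (i in 3:(n + 1)) {
      Ix[i, 1] <- Ix[i - 1, 1] - ext; tbX[i, 1] <- 2L
    }
  }
  if (m >= 1) {
    Iy[1, 2] <- -open[1]; tbY[1, 2] <- 1L
    if (m >= 2) for (j in 3:(m + 1)) {
      Iy[1, j] <- Iy[1, j - 1] - ext; tbY[1, j] <- 2L
    }
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- S[i - 1, j - 1]
      # diag: tie order M > Ix > Iy
      best <- M[i - 1, j - 1]; who <- 1L
      if (Ix[i - 1, j - 1] > best) { best <- Ix[i - 1, j - 1]; who <- 2L }
      if (Iy[i - 1, j - 1] > best) { best <- Iy[i - 1, j - 1]; who <- 3L }
      M[i, j] <- best + s; tbM[i, j] <- who
      # Ix: target residue i-1 aligned to gap (insertion after template j-1);
      # a fresh opening may also follow a deletion (Iy) directly
      oI <- if (j - 1 >= 1) openIns[j - 1] else open[1]
      vOpen <- M[i - 1, j] - oI
      vExt <- Ix[i - 1, j] - ext
      vSwit <- Iy[i - 1, j] - oI
      Ix[i, j] <- max(vOpen, vExt, vSwit)
      tbX[i, j] <- if (vOpen >= vExt && vOpen >= vSwit) 1L
        else if (vExt >= vSwit) 2L else 3L
      # Iy: template residue j-1 aligned to gap (deletion opening at j-1)
      wOpen <- M[i, j - 1] - open[j - 1]
      wExt <- Iy[i, j - 1] - ext
      wSwit <- Ix[i, j - 1] - open[j - 1]
      Iy[i, j] <- max(wOpen, wExt, wSwit)
      tbY[i, j] <- if (wOpen >= wExt && wOpen >= wSwit) 1L
        else if (wExt >= wSwit) 2L else 3L
    }
  }
  # also handle first row/col openings for i=2.. j=1 etc. covered above
  ends <- c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  state <- which.max(ends)  # ties: M > Ix > Iy by which.max order
  score <- ends[state]

  ti <- integer(0); si <- integer(0)
  i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    if (state == 1L) {
      ti <- c(i - 1L, ti); si <- c(j - 1L, si)
      prev <- tbM[i, j]; i <- i - 1; j <- j - 1; state <- prev
    } else if (state == 2L) {
      ti <- c(i - 1L, ti); si <- c(NA_integer_, si)
      prev <- tbX[i, j]; i <- i - 1
      state <- if (prev == 1L) 1L else if (prev == 2L) 2L else 3L
    } else {
      ti <- c(NA_integer_, ti); si <- c(j - 1L, si)
      prev <- tbY[i, j]; j <- j - 1
      state <- if (prev == 1L) 1L else if (prev == 2L) 3L else 2L
    }
  }
  new("PairAlignment", targetIdx = as.integer(ti),
      templateIdx = as.integer(si), score = score,
      matrixName = matName, target = target, template = template)
}

#' Identity and similarity statistics of an alignment
#'
#' Percent identity is computed over aligned (both-non-gap) columns:
#' `identical / aligned * 100`. An optional region restricts the statistic to
#' columns whose target and/or template sequence positions fall inside the
#' given ranges (positions before applying numbering offsets).
#'
#' @param aln A [PairAlignment].
#' @param targetRegion,templateRegion Optional `c(lo, hi)` sequence-position
#'   ranges.
#' @param matrix Substitution matrix used for the "similar" count (score > 0).
#' @return List with `alignedColumns`, `identical`, `similar`, `identity`
#'   (percent).
#' @export
alignmentStats <- function(aln, targetRegion = NULL, templateRegion = NULL,
                           matrix = "BLOSUM62") {
  cols <- alignedColumns(aln)
  keep <- rep(TRUE, nrow(cols))
  if (!is.null(targetRegion))
    keep <- keep & !is.na(cols$target) &
      cols$target >= targetRegion[1] & cols$target <= targetRegion[2]
  if (!is.null(templateRegion))
    keep <- keep & !is.na(cols$template) &
      cols$template >= templateRegion[1] & cols$template <= templateRegion[2]
  cols <- cols[keep, , drop = FALSE]
  both <- !is.na(cols$target) & !is.na(cols$template)
  nAligned <- sum(both)
  if (!nAligned) stop("no aligned columns in the requested region")
  sub <- .substitutionMatrix(matrix)
  ident <- sum(cols$targetAA[both] == cols$templateAA[both])
  simil <- sum(sub[cbind(cols$targetAA[both], cols$templateAA[both])] > 0)
  list(alignedColumns = nAligned, identical = ident, similar = simil,
       identity = 100 * ident / nAligned)
}

#' Core conservation across an alignment
#'
#' Counts template structural-core residues whose aligned target residue is
#' hydrophobic. Core residues aligned to a gap contribute to `nCore` only.
#'
#' @param aln A [PairAlignment].
#' @param templateCorePositions Integer vector of template sequence positions
#'   in the core (positions before applying the numbering offset), e.g.
#'   core residue numbers minus `template@offset`.
#' @param hydrophobic Hydrophobic set, default [hydrophobicSet()].
#' @return List with `nCore`, `nHydrophobicAligned` and `fraction`.
#' @export
coreConservation <- function(aln, templateCorePositions,
                             hydrophobic = hydrophobicSet()) {
  cols <- alignedColumns(aln)
  inCore <- !is.na(cols$template) & cols$template %in% templateCorePositions
  nCore <- length(unique(cols$template[inCore]))
  hit <- inCore & !is.na(cols$target) & cols$targetAA %in% hydrophobic
  nHyd <- length(unique(cols$template[hit]))
  list(nCore = nCore, nHydrophobicAligned = nHyd,
       fraction = if (nCore) nHyd / nCore else NA_real_)
}
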