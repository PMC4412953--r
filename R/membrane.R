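# membrane_charge: net formal charge, exposed basic surface patches,
# hydropathy-based transmembrane segments and the charge-hydropathy disorder
# heuristic.

.seqChars <- function(x) {
  if (is(x, "SequenceRecord")) strsplit(x@seq, "")[[1]]
  else if (is.character(x) && length(x) == 1) strsplit(toupper(x), "")[[1]]
  else as.character(x)
}

#' Net formal charge of a sequence or residue set
#'
#' Sum of per-residue formal charges (Lys/Arg +1, Asp/Glu -1, His and all
#' others 0 under the default scheme). Nonstandard residues (`X`) contribute
#' 0. Additive over concatenation.
#'
#' @param x A [SequenceRecord], a single string, or a character vector of
#'   one-letter codes.
#' @param scheme A charge scheme as returned by [chargeScheme()].
#' @return Numeric net charge.
#' @export
#' @examples
#' netFormalCharge("KRDE")  # 0
#' netFormalCharge("KKR")   # 3
netFormalCharge <- function(x, scheme = chargeScheme()) {
  ch <- .seqChars(x)
  q <- scheme$charges[ch]
  q[is.na(q)] <- 0
  sum(q)
}

# Side-chain terminal nitrogen coordinates for basic residues: NZ for Lys,
# NH1/NH2 for Arg, (ND1/NE2 for His when included). Falls back to the atom
# farthest from the backbone N when no terminal N is present.
.terminalN <- function(structure, keys, includeHis = FALSE, warnMissing = TRUE) {
  a <- structure@atoms
  akeys <- .resKey(a)
  out <- vector("list", length(keys))
  names(out) <- keys
  termNames <- c("NZ", "NH1", "NH2", if (includeHis) c("ND1", "NE2"))
  for (k in keys) {
    rows <- a[akeys == k, , drop = FALSE]
    term <- rows[rows$elety %in% termNames, , drop = FALSE]
    if (nrow(term)) {
      out[[k]] <- as.matrix(term[, c("x", "y", "z")])
    } else {
      if (warnMissing)
        warning("residue ", k, " lacks a side-chain terminal N; ",
                "using its most distal atom")
      heavy <- rows[toupper(rows$element) != "H", , drop = FALSE]
      nIdx <- which(heavy$elety == "N")
      ref <- if (length(nIdx)) as.numeric(heavy[nIdx[1], c("x", "y", "z")])
      else colMeans(as.matrix(heavy[, c("x", "y", "z")]))
      d <- sqrt(colSums((t(as.matrix(heavy[, c("x", "y", "z")])) - ref)^2))
      out[[k]] <- as.matrix(heavy[which.max(d), c("x", "y", "z")])
    }
  }
  out
}

#' Exposed basic-residue surface patches
#'
#' Single-linkage clustering of exposed (non-buried) Lys/Arg residues: two
#' residues are linked when the minimum distance between their side-chain
#' terminal nitrogens is at most `linkDistance`. Clusters with at least
#' `minSize` members are reported as patches with their terminal-N centroid.
#'
#' @param structure A [PdbStructure].
#' @param profile An [AccessibilityProfile] computed on it.
#' @param linkDistance Single-linkage distance in A (default 15).
#' @param minSize Minimum patch size (default 3).
#' @param includeHis Also treat His as basic (default FALSE).
#' @return A [PatchSet].
#' @export
basicPatch <- function(structure, profile, linkDistance = 15, minSize = 3L,
                       includeHis = FALSE) {
  r <- residueTable(structure)
  basicAA <- c("K", "R", if (includeHis) "H")
  buried <- isBuried(profile)
  cand <- r$key[r$aa %in% basicAA & !buried[r$key]]
  empty <- new("PatchSet", patches = list(),
               centroids = matrix(numeric(0), 0, 3),
               linkDistance = linkDistance, minSize = as.integer(minSize))
  if (length(cand) < minSize) return(empty)
  coords <- .terminalN(structure, cand, includeHis = includeHis)
  n <- length(cand)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ci <- coords[[i]]; cj <- coords[[j]]
    d2 <- outer(rowSums(ci^2), rowSums(cj^2), "+") - 2 * ci %*% t(cj)
    adj[i, j] <- adj[j, i] <- min(d2) <= linkDistance^2
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cmp <- igraph::components(g)
  patches <- list(); cents <- NULL
  for (c0 in seq_len(cmp$no)) {
    mem <- which(cmp$membership == c0)
    if (length(mem) < minSize) next
    patches[[length(patches) + 1L]] <- cand[mem]
    allN <- do.call(rbind, coords[mem])
    cents <- rbind(cents, colMeans(allN))
  }
  if (!length(patches)) return(empty)
  new("PatchSet", patches = patches, centroids = cents,
      linkDistance = linkDistance, minSize = as.integer(minSize))
}

# Windowed mean of a per-residue value; centers at positions
# (w+1)/2 .. n-(w-1)/2 for odd w (general: first full window centered).
.windowMeans <- function(v, w) {
  n <- length(v)
  if (n < w) stop("sequence shorter than window")
  cs <- cumsum(c(0, v))
  (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
}

# Maximal runs of TRUE, merging runs separated by gaps <= mergeGap.
.runsOf <- function(flag, mergeGap = 0L) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  if (!nrow(seg)) return(seg)
  if (mergeGap > 0L && nrow(seg) > 1) {
    keep <- list(seg[1, ])
    for (i in 2:nrow(seg)) {
      last <- keep[[length(keep)]]
      if (seg[i, 1] - last[2] - 1L <= mergeGap)
        keep[[length(keep)]] <- c(last[1], seg[i, 2])
      else keep[[length(keep) + 1L]] <- seg[i, ]
    }
    seg <- do.call(rbind, keep)
  }
  seg
}

#' Hydropathy-based transmembrane segments
#'
#' Sliding-window Kyte-Doolittle mean; window centers whose mean hydropathy
#' reaches `threshold` are collected into maximal runs (runs separated by at
#' most 3 centers are merged) and reported as TM segments. Segment bounds are
#' window-center positions in the record's biological numbering.
#'
#' @param seq A [SequenceRecord] (or string); length >= `window`.
#' @param window Window length (default 19, odd recommended).
#' @param threshold Mean-hydropathy threshold (default 1.6).
#' @return A [SegmentAnnotation] with label `"TM"`.
#' @export
tmSegments <- function(seq, window = 19L, threshold = 1.6) {
  rec <- .asSequenceRecord(seq)
  ch <- .seqChars(rec)
  kd <- kyteDoolittle()[ch]
  kd[is.na(kd)] <- 0  # X residues treated as neutral
  wm <- .windowMeans(kd, window)
  centers <- seq_along(wm) + (window - 1L) %/% 2L
  seg <- .runsOf(wm >= threshold, mergeGap = 3L)
  segs <- if (nrow(seg))
    data.frame(start = centers[seg[, 1]] + rec@offset,
               end = centers[seg[, 2]] + rec@offset,
               label = "TM", stringsAsFactors = FALSE)
  else data.frame(start = integer(0), end = integer(0),
                  label = character(0), stringsAsFactors = FALSE)
  new("SegmentAnnotation", segments = segs,
      method = sprintf("Kyte-Doolittle window %d, threshold %.2f",
                       window, threshold))
}

#' Charge-hydropathy disorder segments
#'
#' A window is labelled disordered when its mean absolute net charge exceeds
#' the charge-hydropathy boundary: `<R> > 2.785 * <H> - 1.151`, with `<H>`
#' the window mean Kyte-Doolittle hydropathy rescaled to 0-1 and `<R>` the
#' absolute value of the window mean formal charge. Boundary equality counts
#' as ordered (strict `>`). Maximal runs of disordered window centers are
#' reported.
#'
#' @param seq A [SequenceRecord] (or string); length >= `window`.
#' @param window Window length (default 21).
#' @return A [SegmentAnnotation] with label `"disordered"`.
#' @export
disorderSegments <- function(seq, window = 21L) {
  rec <- .asSequenceRecord(seq)
  ch <- .seqChars(rec)
  kd <- kyteDoolittle()[ch]; kd[is.na(kd)] <- 0
  q <- chargeScheme()$charges[ch]; q[is.na(q)] <- 0
  H <- (.windowMeans(kd, window) + 4.5) / 9
  R <- abs(.windowMeans(q, window))
  dis <- R > 2.785 * H - 1.151
  centers <- seq_along(H) + (window - 1L) %/% 2L
  seg <- .runsOf(dis)
  segs <- if (nrow(seg))
    data.frame(start = centers[seg[, 1]] + rec@offset,
               end = centers[seg[, 2]] + rec@offset,
               label = "disordered", stringsAsFactors = FALSE)
  else data.frame(start = integer(0), end = integer(0),
                  label = character(0), stringsAsFactors = FALSE)
  new("SegmentAnnotation", segments = segs,
      method = sprintf("charge-hydropathy boundary, window %d", window))
}
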