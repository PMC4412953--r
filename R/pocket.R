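# cleft_map: grid-based pocket detection (protein-solvent-protein scan over 7
# directions), mouth counting via bulk-solvent adjacency, lining residues and
# the per-exon tabulation of cleft residues.

.SCAN_DIRS <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))

# Shift a 3D logical array by integer offset d, filling with FALSE.
.shift3d <- function(a, d) {
  dm <- dim(a)
  if (any(abs(d) >= dm)) return(array(FALSE, dm))
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (d[k] >= 0) {
      dst[[k]] <- (1 + d[k]):dm[k]; src[[k]] <- 1:(dm[k] - d[k])
    } else {
      dst[[k]] <- 1:(dm[k] + d[k]); src[[k]] <- (1 - d[k]):dm[k]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# TRUE where any protein voxel lies at p - t*d for t = 1..L (prefix OR along
# -d, computed by doubling).
.prefixOr <- function(occ, d) {
  L <- max(dim(occ))
  acc <- .shift3d(occ, d)
  s <- 1L
  while (s < L) {
    acc <- acc | .shift3d(acc, d * s)
    s <- 2L * s
  }
  acc
}

# Occupancy grid: voxels within vdW + probe of any heavy polymer atom.
.pocketGrid <- function(structure, spacing, probeRadius, margin = 3,
                        maxGridPoints = 2.5e7) {
  a <- structure@atoms
  heavy <- toupper(a$element) != "H"
  a <- a[heavy, , drop = FALSE]
  if (nrow(a) < 1) stop("structure has no heavy atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- vdwRadius(a$element, onUnknown = "default") + probeRadius
  lo <- apply(xyz, 2, min) - max(rad) - margin * spacing
  hi <- apply(xyz, 2, max) + max(rad) + margin * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  if (prod(as.numeric(dims)) > maxGridPoints)
    stop("grid of ", paste(dims, collapse = "x"),
         " voxels exceeds the memory bound; increase the grid spacing")
  occ <- array(FALSE, dims)
  for (i in seq_len(nrow(xyz))) {
    ctr <- (xyz[i, ] - lo) / spacing + 1
    r <- rad[i] / spacing
    i0 <- pmax(1L, as.integer(floor(ctr - r)))
    i1 <- pmin(dims, as.integer(ceiling(ctr + r)))
    ii <- i0[1]:i1[1]; jj <- i0[2]:i1[2]; kk <- i0[3]:i1[3]
    dx2 <- (ii - ctr[1])^2; dy2 <- (jj - ctr[2])^2; dz2 <- (kk - ctr[3])^2
    box <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    occ[ii, jj, kk] <- occ[ii, jj, kk] | box
  }
  list(occ = occ, origin = lo, dims = dims, spacing = spacing)
}

# Protein-solvent-protein direction counts for every voxel.
.pspCounts <- function(occ) {
  psp <- array(0L, dim(occ))
  for (r in seq_len(nrow(.SCAN_DIRS))) {
    d <- .SCAN_DIRS[r, ]
    encl <- .prefixOr(occ, d) & .prefixOr(occ, -d)
    psp <- psp + (encl & !occ)
  }
  psp
}

.NB26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
.NB26 <- .NB26[rowSums(abs(.NB26)) > 0, , drop = FALSE]

# 26-connected components of a voxel mask; returns integer label array.
.label26 <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  todo <- which(mask)
  cur <- 0L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier)) {
      av <- arrayInd(frontier, dm)
      nbr <- integer(0)
      for (r in seq_len(nrow(.NB26))) {
        p <- av
        p[, 1] <- p[, 1] + .NB26[r, 1]
        p[, 2] <- p[, 2] + .NB26[r, 2]
        p[, 3] <- p[, 3] + .NB26[r, 3]
        ok <- p[, 1] >= 1 & p[, 1] <= dm[1] & p[, 2] >= 1 & p[, 2] <= dm[2] &
          p[, 3] >= 1 & p[, 3] <= dm[3]
        if (!any(ok)) next
        li <- p[ok, 1] + (p[ok, 2] - 1L) * dm[1] +
          (p[ok, 3] - 1L) * dm[1] * dm[2]
        nbr <- c(nbr, li[mask[li] & lab[li] == 0L])
      }
      nbr <- unique(nbr)
      lab[nbr] <- cur
      frontier <- nbr
    }
  }
  lab
}

# Voxels reachable (26-conn) within mask from the bounding-box faces.
.bulkSolvent <- function(mask) {
  dm <- dim(mask)
  onFace <- array(FALSE, dm)
  onFace[c(1, dm[1]), , ] <- TRUE
  onFace[, c(1, dm[2]), ] <- TRUE
  onFace[, , c(1, dm[3])] <- TRUE
  visited <- array(FALSE, dm)
  frontier <- which(mask & onFace)
  visited[frontier] <- TRUE
  while (length(frontier)) {
    av <- arrayInd(frontier, dm)
    nbr <- integer(0)
    for (r in seq_len(nrow(.NB26))) {
      p <- av
      p[, 1] <- p[, 1] + .NB26[r, 1]
      p[, 2] <- p[, 2] + .NB26[r, 2]
      p[, 3] <- p[, 3] + .NB26[r, 3]
      ok <- p[, 1] >= 1 & p[, 1] <= dm[1] & p[, 2] >= 1 & p[, 2] <= dm[2] &
        p[, 3] >= 1 & p[, 3] <= dm[3]
      if (!any(ok)) next
      li <- p[ok, 1] + (p[ok, 2] - 1L) * dm[1] + (p[ok, 3] - 1L) * dm[1] * dm[2]
      nbr <- c(nbr, li[mask[li] & !visited[li]])
    }
    nbr <- unique(nbr)
    visited[nbr] <- TRUE
    frontier <- nbr
  }
  visited
}

# Count mouths of one pocket: 26-components of pocket voxels adjacent to bulk
# solvent (solvent = not occupied and not any pocket voxel).
.countMouthsOnGrid <- function(occ, pocketAll, clusterIdx) {
  dm <- dim(occ)
  solv <- !occ & !pocketAll
  bulk <- .bulkSolvent(solv)
  inCluster <- array(FALSE, dm)
  inCluster[clusterIdx] <- TRUE
  av <- arrayInd(clusterIdx, dm)
  touches <- rep(FALSE, length(clusterIdx))
  for (r in seq_len(nrow(.NB26))) {
    p <- av
    p[, 1] <- p[, 1] + .NB26[r, 1]
    p[, 2] <- p[, 2] + .NB26[r, 2]
    p[, 3] <- p[, 3] + .NB26[r, 3]
    ok <- p[, 1] >= 1 & p[, 1] <= dm[1] & p[, 2] >= 1 & p[, 2] <= dm[2] &
      p[, 3] >= 1 & p[, 3] <= dm[3]
    li <- rep(NA_integer_, length(clusterIdx))
    li[ok] <- p[ok, 1] + (p[ok, 2] - 1L) * dm[1] + (p[ok, 3] - 1L) * dm[1] * dm[2]
    touches <- touches | (!is.na(li) & bulk[li])
  }
  if (!any(touches)) return(0L)
  mouthMask <- array(FALSE, dm)
  mouthMask[clusterIdx[touches]] <- TRUE
  max(.label26(mouthMask))
}

#' Detect structural pockets and clefts
#'
#' LIGSITE-style grid scan: the structure is embedded in a regular grid, atom
#' occupancy extends to the van der Waals radius plus the probe radius, and
#' every solvent voxel is scanned along 7 directions (3 axes + 4 body
#' diagonals). Voxels enclosed by protein on both sides in at least
#' `pspThreshold` directions are pocket voxels; these are clustered by
#' 26-connectivity, clusters smaller than `minPoints` are dropped, and the
#' survivors are returned sorted by volume (descending). Mouth counts and
#' lining residues are filled in for each pocket.
#'
#' @param structure A [PdbStructure] (>= 10 atoms).
#' @param spacing Grid spacing in A (default 1.0).
#' @param pspThreshold Minimum enclosing directions of 7 (default 4).
#' @param minPoints Minimum cluster size in voxels (default 30).
#' @param probeRadius Probe radius added to atom radii (default 1.4 A).
#' @param contactDistance Lining-residue distance (A) passed to
#'   [cleftResidues()] (default 4.0).
#' @param maxGridPoints Memory bound on grid voxels.
#' @return List of [Pocket] objects, largest first.
#' @export
#' @examples
#' tube <- buildPocketConstruct("tube")
#' p <- detectPockets(tube$structure)
#' mouthCount(p[[1]])
detectPockets <- function(structure, spacing = 1.0, pspThreshold = 4L,
                          minPoints = 30L, probeRadius = 1.4,
                          contactDistance = 4.0, maxGridPoints = 2.5e7) {
  if (nrow(structure@atoms) < 10)
    stop("pocket detection needs a structure with at least 10 atoms")
  g <- .pocketGrid(structure, spacing, probeRadius,
                   maxGridPoints = maxGridPoints)
  psp <- .pspCounts(g$occ)
  pocketAll <- !g$occ & psp >= pspThreshold
  if (!any(pocketAll)) return(list())
  lab <- .label26(pocketAll)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minPoints)
  if (!length(keep)) return(list())
  keep <- keep[order(-sizes[keep])]
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    idx <- which(lab == keep[k])
    av <- arrayInd(idx, g$dims)
    pts <- sweep((av - 1) * spacing, 2, g$origin, "+")
    colnames(pts) <- c("x", "y", "z")
    mouths <- .countMouthsOnGrid(g$occ, pocketAll, idx)
    pk <- new("Pocket", points = pts, spacing = spacing,
              volume = nrow(pts) * spacing^3, mouths = as.integer(mouths),
              lining = character(0), gridOrigin = g$origin,
              gridDim = g$dims, pspThreshold = as.integer(pspThreshold),
              probeRadius = probeRadius)
    pk@lining <- cleftResidues(pk, structure,
                               contactDistance = contactDistance)
    out[[k]] <- pk
  }
  out
}

#' Recount the mouths of a pocket
#'
#' Recomputes the number of openings of a pocket to bulk solvent from the
#' structure: bulk solvent is the grid-solvent region (excluding this
#' pocket's voxels) connected to the bounding box; the mouths are the
#' 26-connected components of pocket voxels adjacent to it. Fully enclosed
#' cavities have 0 mouths.
#'
#' @param pocket A [Pocket] from [detectPockets()].
#' @param structure The same [PdbStructure].
#' @return Integer mouth count.
#' @export
countMouths <- function(pocket, structure) {
  g <- .pocketGrid(structure, pocket@spacing, pocket@probeRadius)
  dm <- g$dims
  av <- round(sweep(pocket@points, 2, g$origin) / pocket@spacing) + 1
  idx <- av[, 1] + (av[, 2] - 1) * dm[1] + (av[, 3] - 1) * dm[1] * dm[2]
  idx <- as.integer(idx)
  pocketMask <- array(FALSE, dm)
  pocketMask[idx] <- TRUE
  as.integer(.countMouthsOnGrid(g$occ, pocketMask, idx))
}

#' Residues lining a pocket
#'
#' Residues with at least one heavy atom within `contactDistance` of any
#' pocket grid point.
#'
#' @param pocket A [Pocket].
#' @param structure The [PdbStructure] it was detected on.
#' @param contactDistance Contact distance in A (default 4.0).
#' @return Character vector of residue keys (empty for an empty pocket or a
#'   non-positive distance).
#' @export
cleftResidues <- function(pocket, structure, contactDistance = 4.0) {
  pts <- pocket@points
  if (!nrow(pts) || contactDistance <= 0) return(character(0))
  a <- structure@atoms
  heavy <- toupper(a$element) != "H"
  a <- a[heavy, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  keys <- .resKey(a)
  hit <- logical(nrow(a))
  # block over pocket points to bound memory
  step <- max(1L, floor(5e6 / nrow(a)))
  cd2 <- contactDistance^2
  i <- 1L
  while (i <= nrow(pts)) {
    j <- min(i + step - 1L, nrow(pts))
    blk <- pts[i:j, , drop = FALSE]
    d2 <- outer(rowSums(xyz^2), rowSums(blk^2), "+") -
      2 * xyz %*% t(blk)
    hit <- hit | (.rowMins(d2) <= cd2)
    i <- j + 1L
  }
  sort(unique(keys[hit]))
}

# row minima without extra dependencies
.rowMins <- function(m) do.call(pmin, c(as.data.frame(m), na.rm = TRUE))

#' Tabulate cleft residues by exon
#'
#' Counts lining residues per exon with percentage fractions (one decimal).
#' Residues falling outside every exon range are collected in an
#' `"unassigned"` row with a warning.
#'
#' @param residues Character vector of residue keys (`"A:123"`) or integer
#'   residue positions (FL numbering).
#' @param exonMap An [ExonMap].
#' @return `data.frame` with columns `exon_id`, `count`, `fraction`; the
#'   total count is stored in attribute `"total"`.
#' @export
#' @examples
#' em <- packagedFixtures()$exonMap
#' tabulateByExon(c(60, 110, 111), em)
tabulateByExon <- function(residues, exonMap) {
  pos <- if (is.character(residues))
    as.integer(sub("^.*:", "", sub("[A-Za-z]+$", "", residues)))
  else as.integer(residues)
  e <- exonTable(exonMap)
  ex <- exonOf(pos, exonMap)
  if (any(is.na(ex)) && length(pos))
    warning(sum(is.na(ex)), " residue(s) outside all exon ranges: ",
            paste(pos[is.na(ex)], collapse = ", "))
  ex[is.na(ex)] <- "unassigned"
  total <- length(pos)
  ids <- c(e$exon_id[e$exon_id %in% ex],
           if ("unassigned" %in% ex) "unassigned")
  counts <- vapply(ids, function(i) sum(ex == i), integer(1))
  frac <- if (total) round(100 * counts / total, 1) else numeric(length(ids))
  out <- data.frame(exon_id = ids, count = as.integer(counts),
                    fraction = frac, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}
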