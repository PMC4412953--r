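# Shared oracles and construct helpers for the test suite.

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Independent brute-force global aligner: plain recursion over all monotone
# alignments with affine gaps (gap of length L costs open + (L-1) * extend;
# insertion runs take the open penalty of the following template position).
# Only usable for tiny sequences.
bruteAlignScore <- function(target, template, open, extend,
                            sub = .blosum62) {
  tc <- strsplit(target, "")[[1]]
  sc <- strsplit(template, "")[[1]]
  m <- length(sc)
  if (length(open) == 1) open <- rep(open, m)
  openIns <- c(open[-1], open[m])
  rec <- function(i, j, prev) {
    if (i > length(tc) && j > m) return(0)
    out <- -Inf
    if (i <= length(tc) && j <= m)
      out <- max(out, sub[tc[i], sc[j]] + rec(i + 1, j + 1, "M"))
    if (i <= length(tc)) {
      oI <- if (j - 1 >= 1) openIns[j - 1] else open[1]
      cost <- if (prev == "X") extend else oI
      out <- max(out, -cost + rec(i + 1, j, "X"))
    }
    if (j <= m) {
      cost <- if (prev == "Y") extend else open[j]
      out <- max(out, -cost + rec(i, j + 1, "Y"))
    }
    out
  }
  rec(1, 1, "S")
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

randomAASeq <- function(len) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# One pseudo-atom (carbon) per residue at the given coordinates.
pseudoStructure <- function(xyz, id = "construct", aa = "A") {
  n <- nrow(xyz)
  aaVec <- rep_len(aa, n)
  new("PdbStructure", id = id, atoms = data.frame(
    chain = "A", resno = seq_len(n), icode = "",
    resid = aaOneToThree(aaVec), aa = aaVec, elety = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
    stringsAsFactors = FALSE), ligands = list())
}

# Apply a rigid motion (rotation seed + translation) to a structure.
rigidMove <- function(structure, seed = 1, shift = c(5, -3, 11)) {
  at <- atomTable(structure)
  R <- randomRotation(seed = seed)
  m <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- m[, 1] + shift[1]
  at$y <- m[, 2] + shift[2]
  at$z <- m[, 3] + shift[3]
  new("PdbStructure", id = paste0(structure@id, "_moved"), atoms = at,
      ligands = structure@ligands)
}

# A CL-like ligand with a prescribed oxygen-centroid spacing.
ligandWithSpacing <- function(d, id = "CL_fix") {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  g1 <- rbind(c(0, 0, 0), tet * 1.51)
  g2 <- sweep(g1, 2, c(d, 0, 0), "+")
  xyz <- rbind(g1, g2)
  new("CLLigand", id = id, atoms = data.frame(
    name = c("P1", paste0("O1", 1:4), "P2", paste0("O2", 1:4)),
    element = rep(c("P", "O", "P", "O"), c(1, 4, 1, 4)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE),
    groups = list(list(P = 1L, O = 2:5), list(P = 6L, O = 7:10)))
}

# Fixed-width minimal PDB text for parser tests.
miniPdbLines <- function() c(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      12.560   6.351  -6.506  1.00  0.00           C",
  "ATOM      3  C   ALA A   1      13.276   5.259  -5.701  1.00  0.00           C",
  "ATOM      4  O   ALA A   1      12.644   4.275  -5.298  1.00  0.00           O",
  "END")

altlocPdbLines <- function() c(
  "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA ASER A   1       1.458   0.000   0.000  0.60  0.00           C",
  "ATOM      3  CA BSER A   1       9.999   9.999   9.999  0.40  0.00           C",
  "ATOM      4  C   SER A   1       2.009   1.420   0.000  1.00  0.00           C",
  "END")
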