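test_that("Shrake-Rupley areas match analytic spheres and are additive", {
  s1 <- pseudoStructure(matrix(c(0, 0, 0), 1, 3))
  a1 <- sum(computeSasa(s1))
  analytic <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(a1 - analytic) / analytic, 0.02)
  # larger probe can only grow a convex single-atom surface
  expect_gt(sum(computeSasa(s1, probeRadius = 2.0)), a1)
  # two non-interacting atoms are additive
  s2 <- pseudoStructure(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(sum(computeSasa(s2)), 2 * a1, tolerance = 1e-9)
})

test_that("overlapping-pair SASA agrees with a high-density reference", {
  s <- pseudoStructure(rbind(c(0, 0, 0), c(2, 0, 0)))
  a <- sum(computeSasa(s, nSpherePoints = 960L))
  ref <- sum(computeSasa(s, nSpherePoints = 10000L))
  expect_lt(abs(a - ref) / ref, 0.03)
})

test_that("SASA is invariant under rigid motion", {
  h <- buildHelix("MKTLWAGSVDER")
  a0 <- sum(computeSasa(h))
  for (sd in 1:3) {
    a1 <- sum(computeSasa(rigidMove(h, seed = sd, shift = c(7, -2, 3) * sd)))
    expect_lt(abs(a1 - a0), 0.1)
  }
})

test_that("relative accessibility flags burial strictly below the threshold", {
  s <- pseudoStructure(matrix(c(0, 0, 0), 1, 3), aa = "A")
  area <- sum(computeSasa(s))
  mx <- c(A = area / 0.09)
  p <- relativeAccessibility(s, computeSasa(s), maxAsa = mx)
  expect_true(isBuried(p)[["A:1"]])          # 0.09 < 0.1
  # exactly at the threshold: strict <, so not buried
  relExact <- as.numeric(area / (area * 10))
  p2 <- relativeAccessibility(s, computeSasa(s), maxAsa = c(A = area * 10),
                              threshold = relExact)
  expect_false(isBuried(p2)[["A:1"]])
  expect_error(
    relativeAccessibility(s, computeSasa(s), maxAsa = c(G = 104)),
    "absent from max-ASA table")
})

test_that("central Ala of an extended Gly-Ala-Gly peptide is fully exposed", {
  gag <- buildHelix("GAG", phi = -120, psi = 130)
  p <- accessibilityProfile(gag)
  rel <- relAcc(p)[["A:2"]]
  expect_gte(rel, 0.8)
  expect_lte(rel, 1.1)
})

test_that("burial sets shrink monotonically with the threshold", {
  h <- buildHelix(strrep("LAVS", 6))
  area <- computeSasa(h)
  th <- c(0.05, 0.1, 0.3, 0.6)
  sets <- lapply(th, function(t)
    names(which(isBuried(relativeAccessibility(h, area, threshold = t)))))
  for (i in seq_len(length(th) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("residue contacts use minimum heavy-atom distance", {
  near <- pseudoStructure(rbind(c(0, 0, 0), c(4.4, 0, 0)))
  expect_equal(nrow(contactPairs(residueContacts(near))), 1L)
  far <- pseudoStructure(rbind(c(0, 0, 0), c(4.6, 0, 0)))
  expect_equal(nrow(contactPairs(residueContacts(far))), 0L)
  expect_error(residueContacts(near, cutoff = 0), "> 0")
  # brute-force all-pairs oracle on a 10-residue helix
  h <- buildHelix(strrep("A", 10))
  cg <- residueContacts(h, cutoff = 4.5)
  at <- atomTable(h)
  keys <- paste0(at$chain, ":", at$resno)
  expected <- character(0)
  for (i in 1:9) for (j in (i + 1):10) {
    xi <- as.matrix(at[at$resno == i, c("x", "y", "z")])
    xj <- as.matrix(at[at$resno == j, c("x", "y", "z")])
    dmin <- sqrt(min(outer(rowSums(xi^2), rowSums(xj^2), "+") -
                       2 * xi %*% t(xj)))
    if (dmin <= 4.5) expected <- c(expected, paste0("A:", i, "|A:", j))
  }
  got <- sort(paste0(contactPairs(cg)[, 1], "|", contactPairs(cg)[, 2]))
  expect_equal(got, sort(expected))
})

test_that("the structural core is the buried contact components, size >= 2", {
  mkProfile <- function(keys, buried) {
    n <- length(keys)
    new("AccessibilityProfile", residues = data.frame(
      key = keys, chain = "A", resno = seq_len(n), icode = "", aa = "L",
      sasa = 10, relAcc = ifelse(buried, 0.05, 0.5), buried = buried,
      stringsAsFactors = FALSE), threshold = 0.1)
  }
  keys <- paste0("A:", 1:6)
  prof <- mkProfile(keys, c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  cg <- new("ContactGraph",
            pairs = rbind(c("A:1", "A:2"), c("A:2", "A:3"), c("A:4", "A:5"),
                          c("A:5", "A:6")), cutoff = 4.5)
  core <- structuralCore(prof, cg)
  comps <- coreComponents(core)
  expect_equal(length(comps), 1L)          # A:5 is isolated among buried
  expect_setequal(comps[[1]], c("A:1", "A:2", "A:3"))
  expect_true(all(unlist(comps) %in% core@buried))

  noneBuried <- mkProfile(keys, rep(FALSE, 6))
  expect_equal(length(coreComponents(structuralCore(noneBuried, cg))), 0L)
})

test_that("a buried interior face forms one hydrophobic core component", {
  # two stacked rings: inner residues enclosed by an outer shell
  inner <- fibonacciSphere(30) * 3
  outer <- fibonacciSphere(220) * 7.5
  s <- pseudoStructure(rbind(inner, outer), aa = "L")
  p <- accessibilityProfile(s)
  core <- structuralCore(p, residueContacts(s, cutoff = 4.5))
  comps <- coreComponents(core)
  expect_gte(length(comps), 1L)
  innerKeys <- paste0("A:", 1:30)
  hitsPerComp <- vapply(comps, function(cp)
    length(intersect(cp, innerKeys)), integer(1))
  expect_gte(max(hitsPerComp), 24L)  # >= 80 % of the interior in one core
  st <- coreHydrophobicStats(core, s)
  expect_equal(st$hydrophobic, st$total)   # all-Leu construct
  sSer <- pseudoStructure(rbind(inner, outer), aa = "S")
  coreS <- structuralCore(accessibilityProfile(sSer),
                          residueContacts(sSer, cutoff = 4.5))
  expect_equal(coreHydrophobicStats(coreS, sSer)$hydrophobic, 0L)
})
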