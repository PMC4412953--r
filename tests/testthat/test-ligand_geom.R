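test_that("phosphate spacing uses the oxygen-centroid convention", {
  l <- ligandWithSpacing(8.1)
  expect_equal(phosphateSpacing(l), 8.1, tolerance = 1e-9)
  expect_equal(phosphateSpacing(l, mode = "pp"), 8.1, tolerance = 1e-9)
  expect_lt(phosphateSpacing(l, mode = "min_oo"), 8.1)
  expect_equal(phosphateSpacing(ligandWithSpacing(0)), 0)
  bad <- new("CLLigand", id = "bad", atoms = l@atoms,
             groups = l@groups[1])
  expect_error(phosphateSpacing(bad), "exactly 2")
})

test_that("spacing is invariant under rigid motion", {
  l <- makeClLigands(1, seed = 5)[[1]]
  R <- randomRotation(seed = 9)
  a <- l@atoms
  m <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- m[, 1] + 4; a$y <- m[, 2] - 2; a$z <- m[, 3] + 6
  l2 <- new("CLLigand", id = "moved", atoms = a, groups = l@groups)
  expect_equal(phosphateSpacing(l), phosphateSpacing(l2), tolerance = 1e-6)
})

test_that("aggregate spacing reports sample mean and sd", {
  st <- aggregateSpacing(list(ligandWithSpacing(8.0), ligandWithSpacing(8.2)))
  expect_equal(spacingMean(st), 8.1)
  expect_equal(spacingSd(st), stats::sd(c(8.0, 8.2)))
  one <- aggregateSpacing(list(ligandWithSpacing(7.7)))
  expect_equal(one@n, 1L)
  expect_equal(spacingSd(one), 0)
  expect_error(aggregateSpacing(list()), "empty")
  # identical to brute-force recomputation from the per-ligand list
  ll <- makeClLigands(25, seed = 3)
  st2 <- aggregateSpacing(ll)
  sp <- vapply(ll, phosphateSpacing, numeric(1))
  expect_equal(spacingValues(st2), unname(sp))
  expect_equal(spacingMean(st2), mean(sp))
  expect_equal(spacingSd(st2), stats::sd(sp))
})

test_that("generated ligands recover the survey parameters", {
  ll <- makeClLigands(200, meanSpacing = 8.1, jitterSd = 0.4, seed = 17)
  st <- aggregateSpacing(ll)
  expect_lt(abs(spacingMean(st) - 8.1), 3 * 0.4 / sqrt(200))
  ll0 <- makeClLigands(5, jitterSd = 0, seed = 2)
  expect_equal(vapply(ll0, phosphateSpacing, numeric(1)), rep(8.1, 5))
})

test_that("basic pairs are matched against the spacing reference", {
  ref <- new("SpacingStats", spacings = 8.1, mean = 8.1, sd = 0.4, n = 1L)
  mkLys <- function(resno, x) data.frame(
    chain = "A", resno = resno, icode = "", resid = "LYS", aa = "K",
    elety = c("N", "CA", "NZ"), element = c("N", "C", "N"),
    x = x + c(0, 1.5, 3), y = 0, z = 0, occ = 1, stringsAsFactors = FALSE)
  s <- new("PdbStructure", id = "pairs",
           atoms = rbind(mkLys(1, 0), mkLys(2, 7.4)), ligands = list())
  # NZ atoms sit at x = 3 and x = 10.4, i.e. 7.4 A apart
  pm <- matchBasicPairs(c("A:1", "A:2"), s, ref, tolerance = 3.0)
  expect_equal(nrow(pm), 1L)
  expect_equal(pm$distance, 7.4)
  expect_true(pm$compatible)

  sFar <- new("PdbStructure", id = "far",
              atoms = rbind(mkLys(1, 0), mkLys(2, 13.9)), ligands = list())
  pmFar <- matchBasicPairs(c("A:1", "A:2"), sFar, ref, tolerance = 3.0)
  expect_false(pmFar$compatible)   # 13.9 A vs 8.1 +- 3.0
  pmWide <- matchBasicPairs(c("A:1", "A:2"), sFar, ref, tolerance = 6.0)
  expect_true(pmWide$compatible)

  expect_equal(nrow(matchBasicPairs("A:1", s, ref)), 0L)
  noN <- new("PdbStructure", id = "noN", atoms = rbind(
    mkLys(1, 0), mkLys(2, 10)[1:2, ]), ligands = list())
  expect_warning(pm2 <- matchBasicPairs(c("A:1", "A:2"), noN, ref),
                 "lacks a side-chain")
  expect_equal(nrow(pm2), 0L)
})

test_that("a 10.4 A Lys-Lys separation is cardiolipin-compatible", {
  ref <- new("SpacingStats", spacings = 8.1, mean = 8.1, sd = 0.4, n = 1L)
  lys <- function(resno, nzx) data.frame(
    chain = "A", resno = resno, icode = "", resid = "LYS", aa = "K",
    elety = "NZ", element = "N", x = nzx, y = 0, z = 0, occ = 1,
    stringsAsFactors = FALSE)
  s <- new("PdbStructure", id = "k106k152",
           atoms = rbind(lys(106, 0), lys(152, 10.4)), ligands = list())
  pm <- matchBasicPairs(c("A:106", "A:152"), s, ref, tolerance = 3.0)
  expect_equal(pm$distance, 10.4)
  expect_true(pm$compatible)
})
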