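test_that("gap-open penalties interpolate linearly in template accessibility", {
  gp <- gapProfile(c(0, 0.5, 1, 1.7), gMax = 12, gMin = 4, extend = 1)
  expect_equal(gp@open, c(12, 8, 4, 4))  # accessibility capped at 1
  expect_error(gapProfile(c(0.5), gMax = 4, gMin = 12), "ordering")
  expect_error(gapProfile(c(0.5), gMax = 12, gMin = 1, extend = 2),
               "ordering")
  expect_error(gapProfile(numeric(0)), "empty")
})

test_that("identical sequences align gap-free at 100 % identity", {
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  a <- alignPair(s, s, uniformGapProfile(nchar(s)))
  cols <- alignedColumns(a)
  expect_false(any(is.na(cols$target)) || any(is.na(cols$template)))
  expect_equal(alignmentStats(a)$identity, 100)
})

test_that("alignment scores equal brute-force enumeration on short pairs", {
  set.seed(101)
  for (k in 1:25) {
    t0 <- randomAASeq(sample(2:6, 1))
    s0 <- randomAASeq(sample(2:6, 1))
    o <- sample(5:12, 1)
    a <- alignPair(t0, s0, uniformGapProfile(nchar(s0), open = o, extend = 1))
    expect_equal(alignmentScore(a), bruteAlignScore(t0, s0, o, 1),
                 info = paste(t0, s0, o))
  }
  # position-specific profiles against the same oracle
  for (k in 1:10) {
    t0 <- randomAASeq(sample(2:6, 1))
    s0 <- randomAASeq(sample(2:6, 1))
    gp <- gapProfile(runif(nchar(s0)), gMax = 12, gMin = 4, extend = 1)
    a <- alignPair(t0, s0, gp)
    expect_equal(alignmentScore(a), bruteAlignScore(t0, s0, gp@open, 1),
                 info = paste(t0, s0))
  }
})

test_that("uniform-profile scores match an independent affine aligner", {
  set.seed(202)
  for (k in 1:40) {
    t0 <- randomAASeq(sample(5:30, 1))
    s0 <- randomAASeq(sample(5:30, 1))
    o <- sample(6:14, 1); e <- sample(1:3, 1)
    a <- alignPair(t0, s0, uniformGapProfile(nchar(s0), open = o, extend = e))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(t0), Biostrings::AAString(s0),
      substitutionMatrix = .blosum62, gapOpening = o - e, gapExtension = e,
      type = "global", scoreOnly = TRUE)
    expect_equal(alignmentScore(a), ref, info = paste(t0, s0, o, e))
  }
})

test_that("alignment score is symmetric under sequence swap", {
  set.seed(303)
  for (k in 1:10) {
    t0 <- randomAASeq(12); s0 <- randomAASeq(15)
    a <- alignPair(t0, s0, uniformGapProfile(nchar(s0), open = 10, extend = 1))
    b <- alignPair(s0, t0, uniformGapProfile(nchar(t0), open = 10, extend = 1))
    expect_equal(alignmentScore(a), alignmentScore(b))
  }
})

test_that("raising open penalties never increases the gap count", {
  set.seed(404)
  t0 <- randomAASeq(25); s0 <- randomAASeq(30)
  gaps <- vapply(c(5, 8, 11, 14), function(o) {
    cols <- alignedColumns(alignPair(
      t0, s0, uniformGapProfile(nchar(s0), open = o, extend = 1)))
    sum(is.na(cols$target)) + sum(is.na(cols$template))
  }, numeric(1))
  expect_true(all(diff(gaps) <= 0))
})

test_that("identity statistics count aligned columns only", {
  a <- alignPair("AAAA", "AATT", uniformGapProfile(4, open = 12, extend = 1))
  st <- alignmentStats(a)
  expect_equal(st$alignedColumns, 4L)
  expect_equal(st$identity, 50)
  expect_error(alignmentStats(a, targetRegion = c(50, 60)), "no aligned")
  stReg <- alignmentStats(a, targetRegion = c(1, 2))
  expect_equal(stReg$identity, 100)
})

test_that("core conservation counts hydrophobic-aligned template positions", {
  a <- alignPair("LLLL", "LLLL", uniformGapProfile(4))
  cc <- coreConservation(a, templateCorePositions = c(1, 3))
  expect_equal(cc$nCore, 2L)
  expect_equal(cc$nHydrophobicAligned, 2L)
  expect_equal(cc$fraction, 1)
  # gap-aligned core residues count in nCore only
  b <- alignPair("LL", "LLLLLL", uniformGapProfile(6, open = 5, extend = 1))
  cc2 <- coreConservation(b, templateCorePositions = 1:6)
  expect_equal(cc2$nCore, 6L)
  expect_lte(cc2$nHydrophobicAligned, 2L)
  # polar-aligned core positions do not count
  c0 <- alignPair("SSSS", "LLLL", uniformGapProfile(4))
  expect_equal(coreConservation(c0, 1:4)$nHydrophobicAligned, 0L)
})

test_that("the template HX4D anchor aligns to the target motif on a
           tafazzin-like pair", {
  # template: motif embedded in a hydrophobic frame; target: same motif with
  # diverged surroundings and an insertion
  template <- "LVLHAAAADLVLILVAVL"   # HX4D at template 4..9
  target <- "IAIHSTTTDIGIAGGSILIAIV"  # HX4D at target 4..9, tail insertion
  rel <- rep(0.8, nchar(template))
  rel[4:9] <- 0.05  # motif region buried in the template
  a <- alignPair(target, template, gapProfile(rel))
  cols <- alignedColumns(a)
  hisCol <- which(!is.na(cols$template) & cols$template == 4)
  aspCol <- which(!is.na(cols$template) & cols$template == 9)
  expect_equal(cols$targetAA[hisCol], "H")
  expect_equal(cols$targetAA[aspCol], "D")
})
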