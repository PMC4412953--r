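test_that("net formal charge sums the default scheme and is additive", {
  expect_equal(netFormalCharge("KRDE"), 0)
  expect_equal(netFormalCharge("KKR"), 3)
  expect_equal(netFormalCharge("HHH"), 0)  # His contributes 0 to sums
  set.seed(7)
  a <- randomAASeq(30); b <- randomAASeq(45)
  expect_equal(netFormalCharge(paste0(a, b)),
               netFormalCharge(a) + netFormalCharge(b))
})

test_that("the synthetic modeled domain nets +5 like the tafazzin model", {
  sq <- tazSyntheticSequence()
  ch <- strsplit(sq@seq, "")[[1]]
  dom <- setdiff(41:245, 125:154)  # acyltransferase domain minus exon 5
  expect_equal(netFormalCharge(ch[dom]), 5)
})

test_that("exposed basic residues cluster into patches", {
  s <- buildHelix("SRSSRSSRSS", sidechainN = TRUE)
  p <- accessibilityProfile(s)
  ps <- basicPatch(s, p, linkDistance = 15, minSize = 3L)
  expect_length(patchMembers(ps), 1L)
  expect_setequal(patchMembers(ps)[[1]], c("A:2", "A:5", "A:8"))
  expect_equal(nrow(patchCentroids(ps)), 1L)
  # no basic residues -> empty patch set
  s2 <- buildHelix("SSSSSSSSSS")
  expect_length(patchMembers(basicPatch(s2, accessibilityProfile(s2))), 0L)
})

test_that("buried basic residues are excluded from patches", {
  s <- buildHelix("SRSSRSSRSS", sidechainN = TRUE)
  p <- accessibilityProfile(s)
  res <- accessibilityTable(p)
  res$relAcc[res$key == "A:5"] <- 0.01   # bury one of the three Arg
  res$buried <- res$relAcc < p@threshold
  p2 <- new("AccessibilityProfile", residues = res, threshold = p@threshold)
  ps <- basicPatch(s, p2, linkDistance = 15, minSize = 2L)
  expect_false("A:5" %in% unlist(patchMembers(ps)))
})

test_that("patch geometry is rigid-motion invariant and link-monotone", {
  s <- buildHelix("KSSRSSKSSRSSKSSR", sidechainN = TRUE)
  p <- accessibilityProfile(s)
  ps1 <- basicPatch(s, p, linkDistance = 12, minSize = 1L)
  s2 <- rigidMove(s, seed = 13)
  ps2 <- basicPatch(s2, accessibilityProfile(s2), linkDistance = 12,
                    minSize = 1L)
  expect_equal(lapply(patchMembers(ps1), sort),
               lapply(patchMembers(ps2), sort))
  # with minSize 1 merging can only reduce the patch count
  counts <- vapply(c(5, 10, 20, 40), function(ld)
    length(patchMembers(basicPatch(s, p, linkDistance = ld, minSize = 1L))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("hydropathy windows find exactly the hydrophobic stretch", {
  sq <- paste0(strrep("S", 15), strrep("L", 25), strrep("S", 15))
  seg <- segmentTable(tmSegments(sq))
  expect_equal(nrow(seg), 1L)
  expect_gte(seg$start, 16)
  expect_lte(seg$end, 40)
  expect_equal(nrow(segmentTable(tmSegments(strrep("S", 50)))), 0L)
  # windowed means equal the brute-force average
  set.seed(11)
  v <- kyteDoolittle()[strsplit(randomAASeq(60), "")[[1]]]
  wm <- taz3d:::.windowMeans(v, 19L)
  for (i in c(1, 10, 42))
    expect_equal(unname(wm[i]), mean(v[i:(i + 18)]))
})

test_that("the synthetic sequence has a single N-terminal TM helix", {
  seg <- segmentTable(tmSegments(tazSyntheticSequence()))
  expect_equal(nrow(seg), 1L)
  expect_lte(seg$end, 30)   # N-terminal, matching the designed 7-27 stretch
})

test_that("charge-hydropathy heuristic separates ordered from disordered", {
  expect_equal(nrow(segmentTable(disorderSegments(strrep("V", 40)))), 0L)
  segE <- segmentTable(disorderSegments(strrep("E", 40)))
  expect_equal(nrow(segE), 1L)
  # near the boundary: at most 2 Lys per 21-residue window stays ordered,
  # 3 Lys per window crosses it (strict > comparison)
  ord2 <- paste(rep("XXXXXXXXXXK", 5), collapse = "")    # <= 2 K per window
  expect_equal(nrow(segmentTable(disorderSegments(ord2))), 0L)
  dis3 <- paste(rep("XXXXXXK", 6), collapse = "")        # 3 K per window
  expect_gte(nrow(segmentTable(disorderSegments(dis3))), 1L)
})

test_that("the synthetic exon-5 region is labelled disordered", {
  sq <- tazSyntheticSequence()
  seg <- segmentTable(disorderSegments(sq))
  hit <- seg[seg$start <= 130 & seg$end >= 150, , drop = FALSE]
  expect_equal(nrow(hit), 1L)
})
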