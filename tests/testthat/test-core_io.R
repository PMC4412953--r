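test_that("HGVS-p missense notation parses to one-letter records", {
  r <- parseHgvsP(c("p.Gly197Arg", "p.His69Gln"))
  expect_equal(r$ref, c("G", "H"))
  expect_equal(r$position, c(197L, 69L))
  expect_equal(r$alt, c("R", "Q"))
  expect_error(parseHgvsP("p.Xyz12Ala"), "unknown residue")
  expect_error(parseHgvsP("Gly197Arg"), "malformed")
  expect_error(parseHgvsP("p.Gly197Gly"), "identical")
})

test_that("the packaged mutation table has the published shape", {
  fx <- packagedFixtures()
  m <- fx$mutations
  expect_equal(nrow(m), 39L)
  expect_equal(length(unique(m$position)), 33L)
  # unique positions per exon (text counts 8 sites for exon 2; the table's
  # assignment of Gly80 to exon 2 makes it 9 and is kept)
  posByExon <- tapply(m$position, m$exon, function(p) length(unique(p)))
  expect_equal(as.vector(posByExon[c("2", "3", "4", "5", "6", "7", "8",
                                     "10")]),
               c(9L, 2L, 8L, 1L, 4L, 2L, 6L, 1L))
})

test_that("mutation table reading handles empty and malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("hgvs_p\texon", f)
  expect_equal(nrow(readMutationTable(f)), 0L)
  writeLines(c("hgvs_p\texon", "p.Gly10Arg\t2", "garbage\t3"), f)
  expect_error(readMutationTable(f), "row 2")
  expect_warning(m <- readMutationTable(f, strict = FALSE), "dropped")
  expect_equal(nrow(m), 1L)
  expect_equal(attr(m, "rejected")$row, 2L)
})

test_that("exon maps are validated and sorted", {
  fx <- packagedFixtures()
  e <- exonTable(fx$exonMap)
  e5 <- e[e$exon_id == "5", ]
  expect_equal(c(e5$start, e5$end), c(125L, 154L))
  expect_equal(e5$end - e5$start + 1L, 30L)

  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("exon_id\tstart\tend", "3\t96\t100", "2\t40\t95"), f)
  expect_equal(readExonMap(f)@entries$exon_id, c("2", "3"))
  writeLines(c("exon_id\tstart\tend", "2\t40\t95", "3\t90\t100"), f)
  expect_error(readExonMap(f), "overlap")
  writeLines(c("exon_id\tstart\tend", "2\t95\t40"), f)
  expect_error(readExonMap(f), "start > end")
  writeLines("exon_id\tstart\tend", f)
  expect_equal(nrow(exonTable(readExonMap(f))), 0L)
})

test_that("FL <-> Delta5 numbering conversion follows the exon-5 range", {
  em <- packagedFixtures()$exonMap
  expect_equal(mapNumbering(155L, "fl_to_d5", em), 125L)
  expect_equal(mapNumbering(124L, "fl_to_d5", em), 124L)
  expect_true(is.na(mapNumbering(130L, "fl_to_d5", em)))
  expect_error(mapNumbering(0L, "fl_to_d5", em), ">= 1")
  # round trip is the identity on all defined positions
  fl <- 1:292
  d5 <- mapNumbering(fl, "fl_to_d5", em)
  def <- !is.na(d5)
  expect_equal(mapNumbering(d5[def], "d5_to_fl", em), fl[def])
})

test_that("PDB parsing keeps coordinates and resolves altlocs by occupancy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(miniPdbLines(), f)
  s <- readStructure(f)
  expect_equal(nrow(residueTable(s)), 1L)
  expect_equal(atomTable(s)$x[1], 11.104)
  expect_equal(atomTable(s)$aa[1], "A")

  writeLines(altlocPdbLines(), f)
  s2 <- readStructure(f)
  ca <- atomTable(s2)[atomTable(s2)$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 1.458)  # occupancy 0.6 wins
  expect_equal(ca$occ, 0.6)

  expect_error(readStructure(file.path(tempdir(), "no_such.pdb")),
               "cannot read")
})

test_that("structures round-trip through PDB at coordinate precision", {
  h <- buildHelix("KATLWGSV", sidechainN = TRUE)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(h, f)
  h2 <- readStructure(f)
  expect_equal(nrow(atomTable(h2)), nrow(atomTable(h)))
  d <- abs(as.matrix(atomTable(h2)[, c("x", "y", "z")]) -
             as.matrix(atomTable(h)[, c("x", "y", "z")]))
  expect_lt(max(d), 1e-3 + 1e-9)
})

test_that("FASTA reading returns numbered sequence records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seqA test", "ACDEF", ">seqB", "GHIKL"), f)
  rs <- readFastaSequences(f, offset = 40L)
  expect_equal(names(rs), c("seqA", "seqB"))
  expect_equal(rs$seqA@seq, "ACDEF")
  expect_equal(rs$seqA@offset, 40L)
})
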