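test_that("HX4D motifs are located by sequence scan", {
  hits <- findHX4D("AHAAAADAA")
  expect_equal(hits$his, 2L)
  expect_equal(hits$asp, 7L)
  expect_equal(nrow(findHX4D("AAAA")), 0L)
  # numbering offset propagates
  rec <- new("SequenceRecord", id = "x", seq = "AHAAAADAA", offset = 100L)
  expect_equal(findHX4D(rec)$his, 102L)
  # the synthetic tafazzin sequence has exactly the catalytic pair
  h <- findHX4D(tazSyntheticSequence())
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$his, h$asp), c(69L, 74L))
})

test_that("torsion windows assign helix, strand and coil", {
  h <- buildHelix(strrep("A", 12), phi = -57, psi = -47)
  ssH <- assignSecondaryStructure(h)
  expect_true(all(ssH[2:11] == "H"))   # interior
  expect_true(all(ssH[c(1, 12)] == "C"))  # undefined terminal torsions
  e <- buildHelix(strrep("A", 8), phi = -120, psi = 130)
  ssE <- assignSecondaryStructure(e)
  expect_true(all(ssE[2:7] == "E"))
  # a 2-residue helical run stays coil (run-length rule)
  short <- buildHelix("AAAA", phi = -57, psi = -47)
  expect_true(all(assignSecondaryStructure(short) == "C"))
})

test_that("location classification follows the precedence order", {
  con <- buildPocketConstruct("tube")
  s <- con$structure
  prof <- accessibilityProfile(s)
  pockets <- detectPockets(s)
  lining <- liningResidues(pockets[[1]])
  patches <- basicPatch(s, prof)
  liningPos <- as.integer(sub("A:", "", lining))
  # catalytic beats cleft
  expect_equal(classifyLocation(liningPos[1], catalytic = liningPos[1],
                                cleft = lining, profile = prof,
                                patches = patches, structure = s),
               "catalytic")
  # planted lining residue classifies as cleft
  expect_equal(classifyLocation(liningPos[2], catalytic = integer(0),
                                cleft = lining, profile = prof,
                                patches = patches, structure = s),
               "cleft")
  expect_error(classifyLocation(9999L, integer(0), lining, prof, patches, s),
               "not present")
  # exposed residue far from any patch: surface with a distal qualifier
  hx <- buildHelix("SSSSSSSSSS")
  profH <- accessibilityProfile(hx)
  loc <- classifyLocation(5L, catalytic = integer(0), cleft = character(0),
                          profile = profH,
                          patches = basicPatch(hx, profH), structure = hx)
  expect_equal(as.character(loc), "surface")
  expect_equal(attr(loc, "qualifier"), "distal")
})

test_that("buried non-cleft residues classify as buried", {
  inner <- fibonacciSphere(30) * 3
  outer <- fibonacciSphere(220) * 7.5
  s <- pseudoStructure(rbind(inner, outer), aa = "L")
  prof <- accessibilityProfile(s)
  buriedPos <- which(isBuried(prof))
  expect_gt(length(buriedPos), 0)
  pos <- as.integer(sub("A:", "", names(buriedPos)[1]))
  loc <- classifyLocation(pos, catalytic = integer(0), cleft = character(0),
                          profile = prof,
                          patches = basicPatch(s, prof), structure = s)
  expect_equal(as.character(loc), "buried")
})

test_that("electrostatic and stability flags follow the rule set", {
  f <- effectFlags("H", "Q", "catalytic")
  expect_true(f$electrostatic)   # His has its own charge class
  expect_false(f$stability)
  f <- effectFlags("R", "G", "surface")
  expect_true(f$electrostatic)
  expect_false(f$stability)      # to-Gly rule restricted to cleft/buried
  f <- effectFlags("T", "P", "buried")
  expect_false(f$electrostatic)
  expect_true(f$stability)
  expect_match(paste(f$rules, collapse = " "), "Pro")
  f <- effectFlags("D", "V", "cleft")
  expect_true(f$electrostatic)
  expect_true(f$stability)       # volume change 28.9 A^3 in the cleft
  f <- effectFlags("I", "N", "surface")
  expect_false(f$electrostatic)
  expect_true(f$stability)       # hydrophobic-to-polar at the surface
  f <- effectFlags("L", "H", "cleft")
  expect_true(f$electrostatic)
  expect_false(f$stability)      # 13.5 A^3 below the volume threshold
  # pure function: identical inputs, identical outputs
  expect_identical(effectFlags("G", "R", "buried"),
                   effectFlags("G", "R", "buried"))
})

test_that("proposed effects are a deterministic function of location", {
  expect_equal(proposeEffect("catalytic"), "Catalytic activity")
  expect_equal(proposeEffect("cleft"), "Substrate binding")
  expect_equal(proposeEffect("surface"), "Membrane association")
  expect_equal(proposeEffect("buried"), "Destabilization")
  expect_equal(proposeEffect("Catalytic site"), "Catalytic activity")
  expect_error(proposeEffect("outer space"), "unknown location")
})
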