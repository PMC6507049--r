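test_that("PDB round-trip preserves coordinates to format precision", {
  s <- toy_helix(12, c("5" = "K", "9" = "D"))
  txt <- write_structure(s)
  s2 <- assign_charges(load_structure(txt), termini = FALSE)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  a1 <- s$atoms[order(s$atoms$resno, s$atoms$name), ]
  a2 <- s2$atoms[order(s2$atoms$resno, s2$atoms$name), ]
  expect_lt(max(abs(a2$x - a1$x)), 5.1e-4)  # 3-decimal PDB fields
  expect_lt(max(abs(a2$y - a1$y)), 5.1e-4)
  expect_equal(structure_sequence(s2), structure_sequence(s))
})

test_that("single-ATOM input parses; missing ATOM records error", {
  one <- "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C"
  s <- load_structure(one)
  expect_equal(nrow(s$atoms), 1L)
  expect_error(load_structure("REMARK nothing here"), "ATOM")
})

test_that("alternate locations resolve to highest occupancy, ties to A", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C  AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  C  BALA A   1       4.000   0.000   0.000  0.50  0.00           C")
  s <- load_structure(paste(lines, collapse = "\n"))
  ca <- s$atoms[s$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 2.0)  # higher occupancy B conformer
  cc <- s$atoms[s$atoms$name == "C", ]
  expect_equal(cc$x, 3.0)  # tie -> altloc A
})

test_that("unknown residue types are retained with a warning and no charge", {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  C1  XYZ A   2       5.000   0.000   0.000  1.00  0.00           C")
  expect_warning(s <- load_structure(paste(lines, collapse = "\n")), "XYZ")
  s <- assign_charges(s, termini = FALSE)
  expect_equal(net_charge(s), 0)
  expect_true(all(s$atoms$radius > 0))
})

test_that("net formal charge follows the residue/termini census", {
  # capped (no termini): 3 Asp + 2 Arg -> -1
  s <- make_toy("helix", n = 12,
                substitutions = c("2" = "D", "5" = "D", "8" = "D",
                                  "3" = "R", "10" = "R"))$structure
  expect_equal(net_charge(s), -1)
  # free termini: same sidechains, +1 N-term, -1 C-term -> still -1
  sf <- assign_charges(s, termini = TRUE)
  expect_equal(net_charge(sf), -1)
  # single free lysine: +1 sidechain +1 N-term -1 C-term = +1
  lys <- assign_charges(build_peptide("K", matrix(c(0, 0, 0), 1)))
  expect_equal(net_charge(lys), 1)
  # census identity on the synthetic EPO model
  epo <- epo_bundle_model()
  aa <- strsplit(structure_sequence(epo), "")[[1]]
  census <- sum(aa %in% c("K", "R")) + 1 - sum(aa %in% c("D", "E")) - 1
  expect_equal(net_charge(epo), census)
})

test_that("sequence edits require a wild-type match and shift net charge", {
  s <- toy_helix(12, c("4" = "K", "6" = "K", "9" = "K"))
  expect_equal(structure_sequence(s), "AAAKAKAAKAAA")
  s2 <- apply_sequence_edits(assign_charges(s, termini = FALSE),
                             parse_edits("K4N,K6N,K9N"))
  expect_equal(structure_sequence(s2), "AAANANAANAAA")
  expect_equal(net_charge(s2), net_charge(s) - 3)
  # charge swap E -> K gains +2
  se <- toy_helix(12, c("5" = "E"))
  se2 <- apply_sequence_edits(assign_charges(se, termini = FALSE), "E5K")
  expect_equal(net_charge(se2), net_charge(se) + 2)
  # re-applying an applied edit errors (never silent)
  expect_error(apply_sequence_edits(s2, parse_edits("K4N")), "mismatch")
  # empty edit list is the identity
  expect_identical(apply_sequence_edits(s, s$atoms[0, 0]), s)
})

test_that("the construct sequence carries lysines at the glycosylation sites", {
  sq <- strsplit(epo_sequence(construct = TRUE), "")[[1]]
  expect_equal(sq[c(24, 38, 83)], c("K", "K", "K"))
  nat <- strsplit(epo_sequence(construct = FALSE), "")[[1]]
  expect_equal(nat[c(24, 38, 83, 121, 122)], c("N", "N", "N", "P", "P"))
  expect_equal(nchar(epo_sequence()), 166L)
  # the built model, before edits, matches the construct sequence
  raw <- epo_bundle_model(edits = "")
  expect_equal(structure_sequence(raw), epo_sequence(construct = TRUE))
})

test_that("disulphide detection is distance-based", {
  ca <- matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE)
  s <- build_peptide("CC", ca)
  s <- assign_charges(s)
  sg <- s$atoms[s$atoms$name == "SG", ]
  d <- sqrt(sum((sg[1, c("x", "y", "z")] - sg[2, c("x", "y", "z")])^2))
  ss <- find_disulfides(s)
  expect_equal(nrow(ss), as.integer(d < 2.5))
  # force a bonded pair by moving one SG
  s$atoms[s$atoms$name == "SG", c("x", "y", "z")][2, ] <-
    s$atoms[s$atoms$name == "SG", c("x", "y", "z")][1, ] + c(2.0, 0, 0)
  expect_equal(nrow(find_disulfides(s)), 1L)
})
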