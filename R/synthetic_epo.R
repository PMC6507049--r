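# SYNTHETIC erythropoietin stand-in.
#
# A coordinate model of the mature 166-residue human erythropoietin chain
# built entirely in code: the crystal-construct sequence (the natural
# sequence with the three N-glycosylation sites mutated to lysine, N24K /
# N38K / N83K, and P121N / P122S) threaded onto an idealised up-up-down-down
# four-helix bundle. This is NOT an experimental structure; it reproduces
# the coarse architecture of the EPO fold so that the charge-patch and
# stability machinery can run without any external structure file:
#   - helix boundaries A 4-26, B 56-83, C 90-112, D 138-161;
#   - helix axes on a ~10 A square, A/B up, C/D down;
#   - the long AB crossover loop routed so residue 48 packs against the
#     helix D face near residue 155 (F48 covers V46/L155 in the real fold);
#   - helix phases chosen so E13 faces helix D and the helix D basic
#     cluster (R139/K140/R143/K152/K154, with R150) faces outward/towards
#     helix A, keeping the known contiguous basic surface region intact.
# Loops are smooth splines resampled uniformly, so their CA spacing is
# compressed relative to real peptide geometry where the spline is shorter
# than 3.8 A per residue.

.EPO_SEQ_NATIVE <- paste0(
  "APPRLICDSRVLERYLLEAKEAENITTGCAEHCSLNENITVPDTKVNFYAWKRMEVGQQAVEVWQGLALL",
  "SEAVLRGQALLVNSSQPWEPLQLHVDKAVSGLRSLTTLLRALGAQKEAISPPDAASAAPLRTITADTFRK",
  "LFRVYSNFLRGKLKLYTGEACRTGDR")

#' Sequence of the synthetic EPO model
#'
#' @param construct logical; TRUE (default) returns the crystal-construct
#'   analogue sequence (N24K, N38K, N83K, P121N, P122S relative to the
#'   natural mature sequence), FALSE the natural mature sequence.
#' @return one-letter sequence string (166 residues).
#' @export
epo_sequence <- function(construct = TRUE) {
  s <- strsplit(.EPO_SEQ_NATIVE, "")[[1]]
  if (construct) {
    s[c(24, 38, 83)] <- "K"
    s[121] <- "N"
    s[122] <- "S"
  }
  paste(s, collapse = "")
}

# Segment table of the idealised bundle (residue ranges are mature
# numbering). Loop control points were chosen once, by geometry (avoid
# helix interpenetration; route residue ~48 past helix D near residue 155).
.epo_ca_path <- function() {
  ca <- matrix(NA_real_, 166, 3)
  # helix phases: A so that E13 faces the open A/D corner (-y flank, the rim
  # of the basic patch); D so that K152 faces helix A and R150/K154 the
  # exposed +x/-y face contacted by the AB loop.
  ca[4:26, ] <- helix_ca(23, origin = c(0, 0, 0), axis = c(0, 0, 1),
                         phase = 135)
  ca[56:83, ] <- helix_ca(28, origin = c(0, 10, 0), axis = c(0, 0, 1),
                          phase = 0)
  # C phased so K97 faces away from the helix D face (the basic patch is
  # localised at the A/D interface, not shared with helix C)
  ca[90:112, ] <- helix_ca(23, origin = c(10, 10, 34), axis = c(0, 0, -1),
                           phase = 290)
  ca[138:161, ] <- helix_ca(24, origin = c(10, 0, 36), axis = c(0, 0, -1),
                            phase = 220)
  # N-terminal tail 1-3
  ctrl <- rbind(c(-8, -9, -8), c(-4, -6, -4), ca[4, ])
  ca[1:3, ] <- spline_interior(ctrl, 3)
  # AB crossover loop 27-55, two segments pinned at residue 45 so that
  # residues 46-50 pack against helix D near residue 155 (F48/V46 vs L155)
  ca[45, ] <- c(13, -6, 14)
  ctrl <- rbind(ca[26, ], c(-7, -6, 28), c(-10, -10, 21), c(-6, -13, 13),
                c(2, -13, 7), c(9, -9, 8), ca[45, ])
  ca[27:44, ] <- spline_interior(ctrl, 18)
  ctrl <- rbind(ca[45, ], c(12, -2, 9), c(8, -6, 4), c(0, -8, 0),
                c(-5, -2, -1), ca[56, ])
  ca[46:55, ] <- spline_interior(ctrl, 10)
  # BC loop 84-89 (short, over the top of the bundle)
  ctrl <- rbind(ca[83, ], c(1, 15, 45), c(7, 15, 41), ca[90, ])
  ca[84:89, ] <- spline_interior(ctrl, 6)
  # CD crossover loop 113-137, arcing over the helix C side so it does not
  # run along the exposed helix D face
  ctrl <- rbind(ca[112, ], c(12, 15, -1), c(18, 20, 6), c(23, 17, 18),
                c(21, 12, 30), c(15, 6, 38), ca[138, ])
  ca[113:137, ] <- spline_interior(ctrl, 25)
  # C-terminal tail 162-166 hugging the base of helix D
  ctrl <- rbind(ca[161, ], c(15, -3, 0), c(17, -7, -2), c(19, -11, -3))
  ca[162:166, ] <- spline_interior(ctrl, 5)
  ca
}

#' Synthetic erythropoietin bundle model
#'
#' Builds the synthetic EPO coordinate model (see the package vignette for
#' what it does and does not emulate), applies the construct-to-natural
#' sequence edits used for the wild-type calculations (K24N, K38N, K83N,
#' N121P, S122P), then any requested variant mutations, and assigns radii
#' and formal charges.
#'
#' @param mutations optional variant mutation tokens on top of the edited
#'   wild type, e.g. \code{"E13K"} or \code{"F48D,R150D"}.
#' @param edits sequence-edit tokens applied to the construct sequence
#'   (default the five construct-to-natural edits; \code{""} for none).
#' @return a charged \code{protein_structure} (chain A, residues 1-166).
#' @export
epo_bundle_model <- function(mutations = NULL,
                             edits = "K24N,K38N,K83N,N121P,S122P") {
  s <- build_peptide(epo_sequence(construct = TRUE), .epo_ca_path())
  s <- assign_charges(s)
  if (!is.null(edits) && nzchar(edits)) s <- apply_sequence_edits(s, edits)
  if (!is.null(mutations) && nzchar(mutations)) {
    s <- mutate_structure(s, mutations)
  }
  s
}
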