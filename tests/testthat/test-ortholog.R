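template_16 <- function() toy_helix(16, c("5" = "K", "9" = "E", "12" = "R"))

test_that("aligned FASTA reading validates row lengths", {
  fa <- ">a\nAC-DE\n>b\nACQDE\n"
  aln <- read_alignment(fa)
  expect_equal(names(aln), c("a", "b"))
  expect_equal(unname(nchar(aln)), c(5L, 5L))
  expect_error(read_alignment(">a\nACDE\n>b\nAC\n"), "lengths")
})

test_that("an identity alignment reproduces the template atom-for-atom", {
  tpl <- template_16()
  taln <- structure_sequence(tpl)
  m <- model_from_alignment(tpl, taln, taln, name = "self")
  expect_equal(m$coverage, 1)
  expect_equal(m$n_subst, 0L)
  expect_identical(m$structure$atoms, tpl$atoms)
})

test_that("a single K->E column swaps one sidechain and -2 charge", {
  tpl <- template_16()
  taln <- structure_sequence(tpl)
  q <- strsplit(taln, "")[[1]]
  q[5] <- "E"
  m <- model_from_alignment(tpl, paste(q, collapse = ""), taln)
  expect_equal(m$n_subst, 1L)
  expect_equal(net_charge(m$structure), net_charge(tpl) - 2)
  # untouched residues identical
  same <- m$structure$atoms$resno != 5
  expect_equal(m$structure$atoms$x[same], tpl$atoms$x[tpl$atoms$resno != 5])
})

test_that("gaps delete template residues and insertions are flagged", {
  tpl <- template_16()
  taln <- structure_sequence(tpl)
  # target gap at columns 2-4 -> deletion, coverage 13/16
  q <- strsplit(taln, "")[[1]]
  q[2:4] <- "-"
  m <- model_from_alignment(tpl, paste(q, collapse = ""), taln)
  expect_equal(sort(m$deleted), 2:4)
  expect_equal(m$coverage, 13 / 16)
  expect_false(any(m$structure$atoms$resno %in% 2:4))
  # insertion in the target: template gap column, flagged unmodelled
  taln2 <- paste0(substr(taln, 1, 8), "---", substr(taln, 9, 16))
  q2 <- strsplit(taln2, "")[[1]]
  q2[9:11] <- c("G", "G", "G")
  m2 <- model_from_alignment(tpl, paste(q2, collapse = ""), taln2)
  expect_equal(m2$unmodelled, 9:11)
  expect_equal(m2$coverage, 1)  # all template residues modelled
  # modelled backbone identical to template
  bb <- m2$structure$atoms$name %in% c("N", "CA", "C", "O")
  expect_equal(m2$structure$atoms$x[bb],
               tpl$atoms$x[tpl$atoms$name %in% c("N", "CA", "C", "O")])
  # mismatching template row errors with the offending column
  bad <- sub("K", "W", taln)
  expect_error(model_from_alignment(tpl, taln, bad), "column")
})

test_that("survey of the template equals the direct profile", {
  tpl <- template_16()
  tab <- survey(list(tpl), threshold = 80, dots_per_atom = 128,
                sweeps = 500, burn_in = 100, seed = 3)
  expect_equal(nrow(tab), 1L)
  surf <- link_neighbours(build_dot_surface(tpl, dots_per_atom = 128))
  prof <- solubility_profile(
    segment_patches(surf, surface_potential(surf, tpl)), 80)
  expect_equal(tab$ratio, prof$ratio, tolerance = 1e-12)
})

test_that("identical models give identical survey rows; histogram conserves", {
  tpl <- template_16()
  taln <- structure_sequence(tpl)
  aln <- c(tpl = taln, a = taln, b = taln, c = taln)
  models <- models_from_alignment(tpl, aln, "tpl")
  tab <- survey(models, threshold = 80, dots_per_atom = 128,
                sweeps = 500, burn_in = 100, seed = 3)
  expect_equal(nrow(tab), 3L)
  expect_equal(length(unique(tab$ratio)), 1L)
  expect_equal(length(unique(tab$pHstab)), 1L)
  h <- attr(tab, "histogram")
  expect_equal(sum(h$count), nrow(tab))
})

test_that("charge substitutions spread the ratio distribution", {
  tpl <- template_16()
  taln <- structure_sequence(tpl)
  q <- strsplit(taln, "")[[1]]
  variants <- vapply(1:6, function(i) {
    v <- q
    v[5] <- c("K", "E", "K", "Q", "K", "R")[i]
    v[12] <- c("R", "R", "D", "R", "N", "K")[i]
    paste(v, collapse = "")
  }, "")
  aln <- c(tpl = taln, structure(variants, names = paste0("v", 1:6)))
  models <- models_from_alignment(tpl, aln, "tpl")
  tab <- survey(models, threshold = 80, dots_per_atom = 128,
                phstab = FALSE)
  expect_gt(stats::sd(tab$ratio), 0)
  same <- survey(rep(list(tpl), 6), threshold = 80, dots_per_atom = 128,
                 phstab = FALSE)
  expect_gt(stats::sd(tab$ratio), stats::sd(same$ratio))
})

test_that("identity-based row ordering clusters duplicates together", {
  aln <- c(a = "AAAA", b = "AAAT", c = "GGGG", d = "GGGT")
  ord <- order_by_identity(aln)
  pos <- match(c("a", "b", "c", "d"), ord)
  expect_equal(abs(pos[1] - pos[2]), 1L)
  expect_equal(abs(pos[3] - pos[4]), 1L)
})
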