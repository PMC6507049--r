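test_that("a uniform neutral field gives one HYD patch covering everything", {
  toy <- make_toy("single_sphere")
  surf <- link_neighbours(build_dot_surface(toy$structure))
  pat <- segment_patches(surf, rep(0, nrow(surf$dots)))
  expect_equal(nrow(pat$patches), 1L)
  expect_equal(pat$patches$sign, "HYD")
  expect_equal(pat$posQmax, 0)
  expect_equal(pat$negQmax, 0)
  expect_equal(pat$hydmax, surface_area(surf), tolerance = 1e-9)
})

test_that("a forced positive hemisphere forms one POS patch of half the area", {
  toy <- make_toy("single_sphere")
  surf <- link_neighbours(build_dot_surface(toy$structure, dots_per_atom = 512))
  phi <- ifelse(surf$dots$z > 0, 30, 0)
  pat <- segment_patches(surf, phi)
  pos <- pat$patches[pat$patches$sign == "POS", ]
  expect_equal(nrow(pos), 1L)
  expect_equal(pos$area, surface_area(surf) / 2, tolerance = 0.02)
})

test_that("patch areas partition the total surface area", {
  s <- toy_helix(15, c("4" = "K", "8" = "D", "12" = "R"))
  surf <- link_neighbours(build_dot_surface(s))
  phi <- surface_potential(surf, s)
  pat <- segment_patches(surf, phi)
  expect_equal(sum(pat$patches$area), surface_area(surf), tolerance = 1e-9)
  expect_equal(sum(pat$patches$n_dots), nrow(surf$dots))
})

test_that("patch partitions match a brute-force components oracle", {
  set.seed(11)
  for (k in 1:5) {
    toy <- make_toy("dumbbell", separation = runif(1, 3, 6),
                    radii = c(1.9, 1.7))
    surf <- link_neighbours(build_dot_surface(toy$structure,
                                              dots_per_atom = 64))
    phi <- rnorm(nrow(surf$dots), 0, 30)
    pat <- segment_patches(surf, phi)
    cls <- ifelse(phi > 25, "POS", ifelse(phi < -25, "NEG", "HYD"))
    lab <- brute_components_oracle(as.matrix(surf$dots[, c("x", "y", "z")]),
                                   cls, surf$link_distance)
    expect_identical(canon_partition(pat$assignment), canon_partition(lab))
  }
})

test_that("contour boundaries follow the strict/closed convention", {
  toy <- make_toy("single_sphere")
  surf <- link_neighbours(build_dot_surface(toy$structure, dots_per_atom = 32))
  phi <- rep(25, nrow(surf$dots))  # exactly on the contour -> HYD
  pat <- segment_patches(surf, phi)
  expect_equal(pat$posQmax, 0)
  expect_equal(pat$hydmax, surface_area(surf), tolerance = 1e-9)
  phi2 <- rep(-25, nrow(surf$dots))
  expect_equal(segment_patches(surf, phi2)$negQmax, 0)
})

test_that("solubility profile applies the strict ratio > 1 rule", {
  fake <- list(posQmax = 149, hydmax = 10)
  expect_equal(solubility_profile(fake, 100)$prediction, "insoluble")
  expect_equal(solubility_profile(fake, 100)$ratio, 1.49)
  expect_equal(solubility_profile(list(posQmax = 47, hydmax = 0), 100)$prediction,
               "soluble")
  expect_equal(solubility_profile(list(posQmax = 100, hydmax = 0), 100)$prediction,
               "soluble")  # exactly 1.0 is soluble
  expect_error(solubility_profile(fake, 0), "> 0")
  # prediction invariant under common rescaling
  p1 <- solubility_profile(list(posQmax = 120, hydmax = 0), 90)
  p2 <- solubility_profile(list(posQmax = 1200, hydmax = 0), 900)
  expect_equal(p1$ratio, p2$ratio)
  expect_equal(p1$prediction, p2$prediction)
})

test_that("threshold calibration maximises balanced accuracy", {
  cal <- calibrate_threshold(c(10, 20, 30, 40), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(cal$threshold, 25)
  expect_equal(cal$balanced_accuracy, 1)
  # inverted labels: best achievable is chance, with a warning
  expect_warning(inv <- calibrate_threshold(c(10, 20), c(TRUE, FALSE)),
                 "chance")
  expect_equal(inv$balanced_accuracy, 0.5)
  # random datasets agree with the exhaustive oracle
  set.seed(23)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    sizes <- round(runif(n, 0, 100), 1)
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    cal <- suppressWarnings(calibrate_threshold(sizes, labels))
    oracle <- brute_threshold_oracle(sizes, labels)
    expect_equal(cal$balanced_accuracy, oracle$balanced)
    expect_equal(cal$threshold, oracle$threshold)
  }
  expect_error(calibrate_threshold(c(1, 2), c(TRUE, TRUE)), "both")
  # string labels are accepted
  cal2 <- calibrate_threshold(c(5, 50), c("soluble", "insoluble"))
  expect_equal(cal2$threshold, 27.5)
})

test_that("adding a like charge near the largest positive patch never shrinks it", {
  base <- make_toy("charge_lattice", nside = 2, spacing = 8,
                   lattice_charges = data.frame(index = 1, q = 2))
  s <- base$structure
  surf <- link_neighbours(build_dot_surface(s))
  phi <- surface_potential(surf, s)
  p0 <- segment_patches(surf, phi)$posQmax
  # add +1 next to the charged node (same surface, extra source charge)
  phi2 <- phi + potential_at_points(data.frame(x = 1.2, y = 1.2, z = 1.2,
                                               q = 1),
                                    as.matrix(surf$dots[, c("x", "y", "z")]),
                                    es_params())
  p1 <- segment_patches(surf, phi2)$posQmax
  expect_gte(p1, p0)
})

test_that("segmentation demands an aligned field and a neighbour graph", {
  toy <- make_toy("single_sphere")
  surf <- build_dot_surface(toy$structure)
  expect_error(segment_patches(surf, rep(0, nrow(surf$dots))), "neighbour")
  surf <- link_neighbours(surf)
  expect_error(segment_patches(surf, c(0, 0)), "length")
})
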