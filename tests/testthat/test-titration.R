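RTc <- 8.314462618e-3 * 298.15

test_that("a single site titrates as Henderson-Hasselbalch in the exact path", {
  sites <- data.frame(chain = "A", resno = 1, type = "ASP", pKa = 4,
                      q0 = -1, x = 0, y = 0, z = 0)
  grid <- seq(1, 8, 0.5)
  te <- titrate_exact(sites, matrix(0, 1, 1), grid)
  expect_equal(as.numeric(te$fraction), hh_frac(4, grid), tolerance = 1e-12)
  expect_equal(te$fraction[1, grid == 4], 0.5)
  # base behaves identically under the shared signed formula
  base <- data.frame(chain = "A", resno = 1, type = "LYS", pKa = 10.4,
                     q0 = 0, x = 0, y = 0, z = 0)
  tb <- titrate_exact(base, matrix(0, 1, 1), grid)
  expect_equal(as.numeric(tb$fraction), hh_frac(10.4, grid),
               tolerance = 1e-12)
})

test_that("distant sites titrate independently", {
  sys <- list(sites = rbind(
    data.frame(chain = "A", resno = 1, type = "ASP", pKa = 4, q0 = -1,
               x = 0, y = 0, z = 0),
    data.frame(chain = "A", resno = 2, type = "LYS", pKa = 10.4, q0 = 0,
               x = 50, y = 0, z = 0)))
  W <- interaction_matrix(sys$sites, es_params())
  grid <- seq(0, 14, 0.5)
  te <- titrate_exact(sys$sites, W, grid)
  expect_lt(max(abs(te$fraction[1, ] - hh_frac(4, grid))), 1e-3)
  expect_lt(max(abs(te$fraction[2, ] - hh_frac(10.4, grid))), 1e-3)
})

test_that("two coupled acids match the hand-computed 4-state partition function", {
  w <- 5  # kJ/mol between the two deprotonated (-1,-1) charges
  sites <- data.frame(chain = "A", resno = 1:2, type = "ASP",
                      pKa = c(4, 4.4), q0 = -1,
                      x = c(0, 4), y = 0, z = 0)
  W <- matrix(c(0, w, w, 0), 2, 2)
  grid <- seq(2, 7, 0.25)
  te <- titrate_exact(sites, W, grid)
  for (i in seq_along(grid)) {
    f1 <- log(10) * RTc * (grid[i] - 4)
    f2 <- log(10) * RTc * (grid[i] - 4.4)
    # states (x1,x2): energies with q = q0 + x
    E <- c(w,            # 00: both deprotonated, (-1)(-1) w
           f1, f2,       # 10 / 01: one neutralised
           f1 + f2)      # 11
    z <- exp(-E / RTc)
    expect_equal(te$fraction[1, i], (z[2] + z[4]) / sum(z), tolerance = 1e-9)
    expect_equal(te$fraction[2, i], (z[3] + z[4]) / sum(z), tolerance = 1e-9)
    expect_equal(te$G[i], -RTc * log(sum(z)), tolerance = 1e-9)
  }
})

test_that("Monte Carlo titration is seed-reproducible and matches exact", {
  sys <- rand_site_system(8, seed = 101)
  grid <- seq(0, 14, 0.5)
  t1 <- titrate_mc(sys$sites, sys$W, grid, sweeps = 4000, burn_in = 400,
                   seed = 5)
  t2 <- titrate_mc(sys$sites, sys$W, grid, sweeps = 4000, burn_in = 400,
                   seed = 5)
  expect_identical(t1$fraction, t2$fraction)
  te <- titrate_exact(sys$sites, sys$W, grid)
  expect_lt(max(abs(t1$fraction - te$fraction)), 0.015)
  # different seed: same physics within Monte Carlo error
  t3 <- titrate_mc(sys$sites, sys$W, grid, sweeps = 4000, burn_in = 400,
                   seed = 6)
  expect_lt(max(abs(t3$fraction - te$fraction)), 0.015)
  expect_false(identical(t1$fraction, t3$fraction))
})

test_that("thermodynamic integration reproduces the exact free energy", {
  sys <- rand_site_system(6, seed = 55)
  grid <- seq(0, 14, 0.25)
  te <- titrate_exact(sys$sites, sys$W, grid)
  tm <- titrate_mc(sys$sites, sys$W, grid, sweeps = 8000, burn_in = 800,
                   seed = 9)
  # compare G differences relative to the acidic anchor
  dG_e <- te$G - te$G[1]
  dG_m <- tm$G - tm$G[1]
  expect_lt(max(abs(dG_e - dG_m)), 0.6)  # kJ/mol, MC + trapezoid error
  # and the anchors themselves agree (fully-protonated dominance at pH 0)
  expect_lt(abs(te$G[1] - tm$G[1]), 0.1)
})

test_that("site models count, classify and couple sites correctly", {
  # one each of D, E, H, K, R, Y, C plus free termini -> 9 sites
  ca <- helix_ca(7)
  s <- assign_charges(build_peptide("DEHKRYC", ca))
  m <- build_site_model(s)
  expect_equal(nrow(m$sites), 9L)
  expect_setequal(unique(m$sites$type),
                  c("ASP", "GLU", "HIS", "LYS", "ARG", "TYR", "CYS",
                    "NTERM", "CTERM"))
  expect_equal(m$W, t(m$W))
  expect_equal(diag(m$W), rep(0, 9))
  expect_true(all(m$W[upper.tri(m$W)] > 0))
  # disulphide-bonded cysteines are excluded
  s2 <- assign_charges(build_peptide("CAC", helix_ca(3)))
  s2$atoms[s2$atoms$name == "SG" & s2$atoms$resno == 3, c("x", "y", "z")] <-
    s2$atoms[s2$atoms$name == "SG" & s2$atoms$resno == 1, c("x", "y", "z")] +
    c(2, 0, 0)
  s2$disulfides <- find_disulfides(s2)
  m2 <- build_site_model(s2)
  expect_false("CYS" %in% m2$sites$type)
})

test_that("pHstab is zero for identical models and carries the right sign", {
  sys <- rand_site_system(5, seed = 77)
  grid <- seq(0, 14, 0.25)
  t0 <- titrate_exact(sys$sites, matrix(0, 5, 5), grid)
  expect_equal(ph_stability(t0, t0, 7)$pHstab, 0)
  # attractive Asp/Lys contact pair stabilises
  pair <- rbind(
    data.frame(chain = "A", resno = 1, type = "ASP", pKa = 4, q0 = -1,
               x = 0, y = 0, z = 0),
    data.frame(chain = "A", resno = 2, type = "LYS", pKa = 10.4, q0 = 0,
               x = 4, y = 0, z = 0))
  W <- interaction_matrix(pair, es_params())
  tf <- titrate_exact(pair, W, grid)
  tu <- titrate_exact(pair, matrix(0, 2, 2), grid)
  expect_lt(ph_stability(tf, tu, 7)$pHstab, 0)
  # repulsive Lys/Lys contact pair destabilises
  kk <- pair; kk$type <- "LYS"; kk$pKa <- 10.4; kk$q0 <- 0
  tfk <- titrate_exact(kk, W, grid)
  tuk <- titrate_exact(kk, matrix(0, 2, 2), grid)
  expect_gt(ph_stability(tfk, tuk, 7)$pHstab, 0)
  # grid mismatch is an error
  tshort <- titrate_exact(pair, W, seq(0, 14, 0.5))
  expect_error(ph_stability(tf, tshort, 7), "grid")
})

test_that("enumeration refuses oversized systems and handles empty ones", {
  sys <- rand_site_system(3, seed = 1)
  big <- sys$sites[rep(1, 21), ]
  expect_error(titrate_exact(big, matrix(0, 21, 21), c(7)), "20 sites")
  empty <- sys$sites[0, ]
  te <- titrate_exact(empty, matrix(0, 0, 0), c(6, 7))
  expect_equal(te$G, c(0, 0))
  expect_error(titrate_mc(sys$sites, sys$W, c(7), sweeps = 100,
                          burn_in = 10), "seed")
})
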