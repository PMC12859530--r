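# Monte-Carlo ensemble geometry, permeability calibration and PGSE decay

test_that("ensemble seed count matches the cell density", {
  # 1e6 cells/uL is exactly 1 cell per 1000 um^3
  ens <- build_ensemble(rho = 1e6, V = 0.6, box_edge = 40, seed = 1)
  expect_equal(ens$n_cells, round(40^3 / 1000))
  expect_error(build_ensemble(rho = 1e6, V = 0.6, box_edge = 20, seed = 1),
               "degenerate")
  expect_error(build_ensemble(rho = 20e5, V = 0.6, box_edge = 40, seed = 1),
               "infeasible")
})

test_that("shrinkage hits the target intracellular fraction", {
  ens <- build_ensemble(rho = 10.4e5, V = 0.85, box_edge = 45, seed = 7)
  expect_equal(ens$vi, 0.884)
  # rejection-sampling oracle over the generated geometry
  frac <- intracellular_fraction(ens, n = 1e5, seed = 2)
  expect_lt(abs(frac - 0.884), 0.01)
  # mean shrunk-cell volume equals V within 2 percent:
  # vi * box^3 / n_cells, converted um^3 -> pL
  mean_V <- ens$vi * ens$box_edge^3 / ens$n_cells / 1000
  expect_lt(abs(mean_V - 0.85) / 0.85, 0.02)
  # unshrunk tessellation is space-filling
  ens1 <- ens
  ens1$shrink_factor <- 1
  expect_equal(intracellular_fraction(ens1, n = 2e4, seed = 3), 1)
})

test_that("ensembles are bit-identical under the same seed", {
  a <- build_ensemble(rho = 10.4e5, V = 0.85, box_edge = 40, seed = 5)
  b <- build_ensemble(rho = 10.4e5, V = 0.85, box_edge = 40, seed = 5)
  expect_identical(a$seeds, b$seeds)
  expect_identical(a$centroids, b$centroids)
})

test_that("permeability calibration meets the 5 percent residence contract", {
  ens <- build_ensemble(rho = 10.4e5, V = 0.85, box_edge = 45, seed = 7)
  expect_identical(as.numeric(calibrate_permeability(ens, 0)), 0)
  p40 <- calibrate_permeability(ens, 40, seed = 3)
  expect_lt(abs(attr(p40, "measured_kio") - 40) / 40, 0.05)
  # independent verification with a fresh seed and walkers
  set.seed(99)
  ver <- madi:::cpp_residence(ens$seeds, ens$centroids, ens$shrink_factor,
                              ens$box_edge, 1.0, attr(p40, "dt"),
                              as.numeric(p40), 8000L, 150)
  k_hat <- madi:::residence_rate(ver) * 1e3
  expect_lt(abs(k_hat - 40) / 40, 0.05)
  # mean residence time ~ 1/k_io = 25 ms
  expect_lt(abs(mean(ver$time[!ver$censored]) - 25) / 25, 0.05)
  # doubling k_io strictly increases the calibrated probability
  p80 <- calibrate_permeability(ens, 80, seed = 3)
  expect_gt(as.numeric(p80), as.numeric(p40))
})

test_that("free-diffusion decay matches exp(-bD) within 3 MC standard errors", {
  prot <- default_protocol()
  p <- tissue_params(0, 0.85, 10.4e5, D_i = 1.0, D_e = 1.0)
  cur <- simulate_decay(NULL, p, prot, n_walkers = 10000, dt = 0.01, seed = 42)
  b_ms <- prot$b_values * 1e-3
  exact <- exp(-(b_ms - b_ms[1]) * 1.0)
  expect_true(all(abs(cur$S - exact) <= 3 * pmax(cur$se, 1e-12)))
})

test_that("decay curves are normalized, reproducible, and exchange-sensitive", {
  prot <- default_protocol()
  rho <- 300e5; V <- 0.02
  ens <- build_ensemble(rho, V, box_edge = (100 / (rho * 1e-9))^(1 / 3),
                        seed = 11)
  dt <- (madi:::cell_diameter(V) / 10)^2 / 6
  pc <- calibrate_permeability(ens, 40, dt = dt, seed = 6)
  ens40 <- set_permeability(ens, pc, 40)
  p40 <- tissue_params(40, V, rho)
  a <- simulate_decay(ens40, p40, prot, n_walkers = 3000, seed = 8)
  b <- simulate_decay(ens40, p40, prot, n_walkers = 3000, seed = 8)
  expect_identical(a$S, b$S)
  expect_equal(a$S[1], 1)
  # uncalibrated ensemble is a state error for kio > 0
  expect_error(simulate_decay(ens, p40, prot, n_walkers = 100, seed = 1),
               "uncalibrated")
  # impermeable cells decay less at high b than permeable ones
  p0 <- tissue_params(0, V, rho)
  c0 <- simulate_decay(ens, p0, prot, n_walkers = 3000, dt = dt, seed = 8)
  expect_gt(c0$S[8], a$S[8])
})

test_that("impermeable-cell signal splits into restricted and hindered pools", {
  prot <- default_protocol()
  rho <- 300e5; V <- 0.02
  ens <- build_ensemble(rho, V, box_edge = (100 / (rho * 1e-9))^(1 / 3),
                        seed = 11)
  dt <- (madi:::cell_diameter(V) / 10)^2 / 6
  p0 <- tissue_params(0, V, rho, D_i = 1.0, D_e = 2.0)
  c0 <- simulate_decay(ens, p0, prot, n_walkers = 8000, dt = dt, seed = 5)
  Si <- attr(c0, "S_intra")
  b_ms <- prot$b_values * 1e-3
  # restricted pool barely decays: far above the free-diffusion envelope
  expect_gt(Si[8] / Si[1], exp(-(b_ms[8] - b_ms[1]) * 1.0))
  # total curve equals the population-weighted sum of the split pools
  fit_i <- stats::lm(log(Si / Si[1]) ~ I(b_ms - b_ms[1]))
  Se <- attr(c0, "S_extra")
  expect_true(all(diff(c0$S) <= 0))
})

test_that("Monte-Carlo decay matches the Karger oracle for small explored cells", {
  # narrow-pulse protocol so exchange acts over ~the modeled diffusion time
  prot <- acquisition_protocol(c(18, 113, 513, 1013, 2013, 3013, 4513, 6013),
                               delta = 1, Delta = 25)
  rho <- 300e5; V <- 0.02
  ens <- build_ensemble(rho, V, box_edge = (100 / (rho * 1e-9))^(1 / 3),
                        seed = 11)
  dt <- (madi:::cell_diameter(V) / 10)^2 / 6
  p0 <- tissue_params(0, V, rho)
  c0 <- simulate_decay(ens, p0, prot, n_walkers = 8000, dt = dt, seed = 5)
  b_ms <- prot$b_values * 1e-3
  Si <- attr(c0, "S_intra"); Se <- attr(c0, "S_extra")
  Da_i <- -stats::coef(stats::lm(log(Si / Si[1]) ~ I(b_ms - b_ms[1])))[[2]]
  Da_e <- -stats::coef(stats::lm(log(Se / Se[1]) ~ I(b_ms - b_ms[1]),
                                 subset = 1:5))[[2]]
  pc <- calibrate_permeability(ens, 40, dt = dt, seed = 6)
  ens40 <- set_permeability(ens, pc, 40)
  p40 <- tissue_params(40, V, rho)
  c40 <- simulate_decay(ens40, p40, prot, n_walkers = 8000, dt = dt, seed = 7)
  kk <- karger_decay(p40, prot, Da_i = Da_i, Da_e = Da_e)
  z <- (c40$S - kk$S) / pmax(c40$se, 1e-12)
  expect_lt(max(abs(z[-1])), 3)
})
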