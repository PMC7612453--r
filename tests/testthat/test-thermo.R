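test_that("Gibbs-Helmholtz curve has its zeros and maximum where it should", {
  p <- row70()
  expect_equal(gibbs_helmholtz(298.2, p), 0)
  # the printed cold-denaturation temperature is a near-zero of the curve
  expect_lt(abs(gibbs_helmholtz(283.1, p)), 0.01)
  # fine-grid maximum as independent oracle for Ts and the peak height
  Tg <- seq(270, 300, by = 1e-3)
  dG <- gibbs_helmholtz(Tg, p)
  expect_equal(max_stability_temp(p), Tg[which.max(dG)], tolerance = 2e-3)
  expect_equal(max(dG), 0.362, tolerance = 1e-2)
  expect_error(gibbs_helmholtz(-5, p), "positive")
  expect_error(gibbs_helmholtz(300, c(28.5, -1, 3.73)), "Tm")
})

test_that("Boltzmann populations invert the free energy correctly", {
  expect_equal(unfolded_fraction(285, 0), 0.5)
  expect_equal(unfolded_fraction(400, 0), 0.5)
  R <- gas_constant_kcal()
  dG <- R * 298.15 * log(7 / 3)
  expect_equal(unfolded_fraction(298.15, dG), 0.300, tolerance = 1e-12)
  expect_equal(unfolded_fraction(298.15, 1e6), 0)
  expect_equal(folded_fraction(298.15, dG), 0.700)
  expect_error(unfolded_fraction(0, 1), "positive")
})

test_that("closed-form Ts matches special cases and rejects dCp <= 0", {
  expect_equal(max_stability_temp(row70()), 290.656, tolerance = 1e-3)
  expect_equal(max_stability_temp(thermo_params(0, 300, 2)), 300)
  # dSm = dCp  =>  Ts = Tm/e
  expect_equal(max_stability_temp(thermo_params(300 * 2, 300, 2)), 300 / exp(1))
  expect_error(max_stability_temp(c(20, 300, -1)), "dCp")
})

test_that("cold-denaturation temperature reproduces printed values", {
  expect_equal(cold_denaturation_temp(row70()), 283.1, tolerance = 0.2 / 283.1)
  expect_equal(cold_denaturation_temp(row61()), 273.9, tolerance = 0.2 / 273.9)
  # root is a true zero to high precision
  tc <- cold_denaturation_temp(row70())
  expect_lt(abs(gibbs_helmholtz(tc, row70())), 1e-9)
  expect_error(cold_denaturation_temp(c(20, 300, 0)), "dCp")
  # very shallow curve: no zero above the floor
  expect_warning(tc2 <- cold_denaturation_temp(thermo_params(20, 300, 0.2)),
                 "no observable cold denaturation")
  expect_true(is.na(tc2))
})

test_that("entropy at Tm is dHm/Tm and matches printed table values", {
  expect_equal(entropy_at_tm(c(19.9, 298.4, 1.58)), 0.067, tolerance = 0.001 / 0.067)
  expect_equal(entropy_at_tm(c(33.1, 299.6, 3.73)), 0.111, tolerance = 0.001 / 0.111)
  expect_equal(entropy_at_tm(thermo_params(0, 300, 1)), 0)
})

test_that("curvature is -dCp/T and matches a finite difference of the curve", {
  expect_equal(curvature(300, c(20, 300, 3.0)), -0.01)
  expect_equal(curvature(280, c(20, 300, 0)), 0)
  p <- row70()
  h <- 0.01
  fd <- (gibbs_helmholtz(283.1 + h, p) - 2 * gibbs_helmholtz(283.1, p) +
           gibbs_helmholtz(283.1 - h, p)) / h^2
  expect_equal(curvature(283.1, p), fd, tolerance = 1e-6 / abs(fd))
  expect_equal(curvature(283.1, p), -0.01318, tolerance = 1e-3)
  expect_error(curvature(-1, p), "positive")
})

test_that("naive intensity-based stability is the two-state log-odds", {
  expect_equal(naive_stability(310, 0.5), 0)
  expect_equal(naive_stability(298.15, 0.7), 0.502, tolerance = 1e-3)
  expect_error(naive_stability(298.15, 1.0), "strictly inside")
  expect_error(naive_stability(298.15, 0), "strictly inside")
})

test_that("sign structure, maximum and round trips hold over random draws", {
  draws <- random_params(1000)
  n_tc <- 0
  for (i in seq_len(nrow(draws))) {
    p <- suppressWarnings(
      thermo_params(draws$dHm[i], draws$Tm[i], draws$dCp[i]))
    expect_lt(abs(gibbs_helmholtz(p$Tm, p)), 1e-9)
    ts <- max_stability_temp(p)
    # zero derivative at the maximum
    h <- 1e-3
    dslope <- (gibbs_helmholtz(ts + h, p) - gibbs_helmholtz(ts - h, p)) / (2 * h)
    expect_lt(abs(dslope), 1e-6)
    if (!is.na(p$Tc)) {
      n_tc <- n_tc + 1
      expect_lt(abs(gibbs_helmholtz(p$Tc, p)), 1e-9)
      inside <- seq(p$Tc + 0.01, p$Tm - 0.01, length.out = 7)
      expect_true(all(gibbs_helmholtz(inside, p) > 0))
      expect_lt(gibbs_helmholtz(p$Tc - 0.5, p), 0)
      expect_lt(gibbs_helmholtz(p$Tm + 0.5, p), 0)
      expect_true(p$Tc < ts && ts < p$Tm)
    }
    expect_equal(p$dSm * p$Tm, p$dHm)
  }
  expect_gt(n_tc, 500)  # most draws show observable cold denaturation
})

test_that("Ts equals the grid argmax for random draws", {
  draws <- random_params(200, seed = 33)
  step <- 0.01
  for (i in seq_len(nrow(draws))) {
    p <- suppressWarnings(
      thermo_params(draws$dHm[i], draws$Tm[i], draws$dCp[i]))
    Tg <- seq(max(150, p$Ts - 20), p$Ts + 20, by = step)
    expect_lt(abs(p$Ts - Tg[which.max(gibbs_helmholtz(Tg, p))]), 2 * step)
  }
})

test_that("populations round-trip through the naive stability formula", {
  p <- row70()
  T <- default_grid()
  dG <- gibbs_helmholtz(T, p)
  f_F <- folded_fraction(T, dG)
  expect_equal(naive_stability(T, f_F), dG, tolerance = 1e-10)
})

test_that("linear reparameterisation of the curve is exactly invertible", {
  for (p in fittable_params(10)) {
    cc <- gh_linear_coefs(p)
    q <- gh_from_linear(cc["c0"], cc["c1"], cc["dCp"])
    expect_equal(q$dHm, p$dHm, tolerance = 1e-8)
    expect_equal(q$Tm, p$Tm, tolerance = 1e-8)
  }
  # least-squares fit to exact curve values recovers the generator
  p <- row70()
  T <- seq(276, 306, by = 2)
  q <- fit_gibbs_helmholtz_dg(T, gibbs_helmholtz(T, p))
  expect_equal(coef_vec <- c(q$dHm, q$Tm, q$dCp), c(28.5, 298.2, 3.73),
               tolerance = 1e-6)
})

test_that("thermo_params validates inputs and covariance", {
  expect_error(thermo_params(20, -3, 2), "Tm")
  expect_error(thermo_params(20, 300, 2, cov = diag(2)), "3x3")
  asym <- matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3, 3)
  expect_error(thermo_params(20, 300, 2, cov = asym), "symmetric")
  p <- thermo_params(20, 300, 2, cov = diag(c(1, 0.01, 0.04)))
  expect_true(isSymmetric(p$cov))
})
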