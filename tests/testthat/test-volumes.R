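test_that("normalisation divides by the reference peak and guards zeros", {
  s <- volume_series("x", c(280, 290), c(2, 4), c(2, 4))
  expect_equal(normalize_volumes(s)$normalized, c(1, 1))
  s2 <- volume_series("x", c(280, 290), c(3, 1), c(2, 2))
  expect_equal(s2$normalized, c(1.5, 0.5))
  expect_error(volume_series("x", c(280, 290), c(3, 1), c(2, 0)), "290")
  expect_error(volume_series("x", c(290, 280), c(1, 1)), "increasing")
})

test_that("volume-to-population transform matches the hand-worked example", {
  s <- volume_series("demo", c(278, 298, 313), c(10, 8, 2))
  pop <- volumes_to_populations(s, anchor_T = 298, anchor_fraction = 0.70)
  # apparent fractions (V - V_U)/(V_F - V_U) = (1, 0.75, 0), then x 0.70/0.75
  expect_equal(pop$f_F, c(1 * 0.7 / 0.75, 0.70, 0), tolerance = 1e-12)
  expect_equal(pop$f_F + pop$f_U, rep(1, 3))
  expect_equal(attr(pop, "anchor_T"), 298)
})

test_that("degenerate and unanchorable series error clearly", {
  flat <- volume_series("flat", c(278, 288, 298), c(5, 5, 5))
  expect_error(volumes_to_populations(flat), "degenerate|flat")
  # all volume at the unfolded baseline: apparent fraction 0 at the anchor
  down <- volume_series("down", c(278, 288, 298), c(9, 7, 7))
  expect_error(volumes_to_populations(down, anchor_T = 298), "anchor")
})

test_that("exact synthetic volumes round-trip to the generating fractions", {
  p <- row70()
  spec <- synthetic_spec(p, noise_sigma = 0)
  gen <- generate_series(spec)
  pop <- volumes_to_populations(gen$volumes, anchor_T = spec$anchor_T,
                                anchor_fraction = spec$anchor_fraction,
                                v_u_rule = "zero")
  expect_equal(pop$f_F, gen$truth$f_F, tolerance = 1e-10)
})

test_that("anchoring is idempotent", {
  s <- volume_series("demo", c(278, 298, 313), c(10, 8, 2))
  pop1 <- volumes_to_populations(s, anchor_T = 298, anchor_fraction = 0.70)
  # feed the folded populations back through the same transform
  s2 <- volume_series("demo", pop1$temperature, pop1$f_F)
  pop2 <- volumes_to_populations(s2, anchor_T = 298, anchor_fraction = 0.70)
  expect_equal(pop2$f_F, pop1$f_F, tolerance = 1e-12)
})

test_that("noiseless end-to-end fits recover the generator to 1e-6 relative", {
  for (p in fittable_params(50)) {
    spec <- synthetic_spec(p, noise_sigma = 0)
    gen <- generate_series(spec)
    fit <- fit_generated(gen, spec, v_u_rule = "zero")
    expect_false(fit$flagged)
    expect_equal(unname(coef(fit)), c(p$dHm, p$Tm, p$dCp), tolerance = 1e-6)
    expect_lt(max(abs(fit$residuals)), 1e-8)
  }
})

test_that("fit under 3% noise at a fixed seed lands near the generator", {
  p <- row70()
  spec <- synthetic_spec(p, noise_sigma = 0.03, seed = 11)
  fit <- fit_generated(generate_series(spec), spec)
  expect_false(fit$flagged)
  expect_lt(abs(fit$params$Tm - 298.2), 1)
})

test_that("degenerate population series are flagged, never reported silently", {
  T <- default_grid()
  flat <- population_series("flat", T, rep(0.5, length(T)))
  fit <- fit_stability(flat)
  expect_true(fit$flagged)
  expect_false(fit$converged)
  expect_match(fit$flags, "unidentifiable")
  expect_error(fit_stability(population_series("short", c(278, 283, 288, 293, 298, 303),
                                               c(.9, .8, .7, .5, .3, .1))),
               "6 distinct")
})

test_that("the top grid temperature is excluded as the unfolded reference", {
  p <- row70()
  fit <- fit_stability(truth_populations(p))
  expect_equal(fit$excluded, 313)
  expect_false(313 %in% fit$data$temperature)
})

test_that("error propagation matches its closed-form special cases", {
  p <- row70()
  fit <- fit_stability(truth_populations(p))
  # zero covariance -> zero band
  fit0 <- fit
  fit0$params$cov <- matrix(0, 3, 3)
  expect_equal(propagate_errors(fit0, c(280, 290, 300)), rep(0, 3))
  # variance only in dHm, evaluated at Tm: gradient (1 - T/Tm) vanishes
  fit1 <- fit
  fit1$params$cov <- diag(c(4, 0, 0))
  expect_equal(propagate_errors(fit1, p$Tm), 0)
  expect_equal(propagate_errors(fit1, 280), 2 * abs(1 - 280 / p$Tm))
})

test_that("propagated bands agree with a Monte-Carlo oracle", {
  p <- row70()
  Sigma <- matrix(c(1.2, 0.05, 0.3,
                    0.05, 0.04, 0.01,
                    0.3, 0.01, 0.09), 3, 3)
  pc <- thermo_params(p$dHm, p$Tm, p$dCp, cov = Sigma)
  Tg <- c(280, 285, 290, 295, 300)
  band <- propagate_errors(pc, Tg)
  set.seed(99)
  L <- chol(Sigma)
  draws <- matrix(rnorm(3 * 1e5), ncol = 3) %*% L
  mc <- vapply(Tg, function(tt) {
    g <- c(1 - tt / p$Tm,
           p$dHm * tt / p$Tm^2 + p$dCp * (tt / p$Tm - 1),
           (tt - p$Tm) - tt * log(tt / p$Tm))
    sd(draws %*% g)
  }, numeric(1))
  expect_equal(band, mc, tolerance = 0.02)
})

test_that("model-object methods behave like a classic R fit", {
  p <- row70()
  fit <- fit_stability(truth_populations(p, label = "70 Leu"))
  expect_named(coef(fit), c("dHm", "Tm", "dCp"))
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  expect_length(residuals(fit), fit$n_points)
  pr <- predict(fit, c(285, 295), se.fit = TRUE)
  expect_equal(pr$fit, gibbs_helmholtz(c(285, 295), fit$params))
  expect_true(all(pr$se.fit >= 0))
  expect_equal(predict(fit, 290, what = "f_U"),
               unfolded_fraction(290, gibbs_helmholtz(290, fit$params)))
  s <- summary(fit)
  expect_s3_class(s, "summary.stab_fit")
  expect_output(print(fit), "70 Leu")
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "volume_series")
  pf <- tempfile(fileext = ".png")
  grDevices::png(pf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(pf))
})

test_that("volume tables read back in long and wide formats", {
  tmp <- tempfile(fileext = ".tsv")
  df <- data.frame(residue_label = rep(c("a", "b"), each = 3),
                   temperature_K = rep(c(278, 288, 298), 2),
                   volume = c(3, 2, 1, 6, 4, 2),
                   reference_volume = 1)
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  sl <- read_volume_table(tmp)
  expect_named(sl, c("a", "b"))
  expect_equal(sl$b$normalized, c(6, 4, 2))
  # wide format with a reference row
  tmpw <- tempfile(fileext = ".tsv")
  wide <- data.frame(residue_label = c("a", "reference"),
                     T278 = c(3, 2), T288 = c(2, 2), T298 = c(1, 2))
  write.table(wide, tmpw, sep = "\t", quote = FALSE, row.names = FALSE)
  sw <- read_volume_table(tmpw)
  expect_equal(sw$a$normalized, c(1.5, 1, 0.5))
})
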