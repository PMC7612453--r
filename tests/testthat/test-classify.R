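make_rad <- function(labels, rad_values) {
  structure(data.frame(residue_label = labels, RAD = rad_values,
                       stringsAsFactors = FALSE),
            class = c("rad_table", "data.frame"))
}

test_that("the reference curve is the mean of its members' populations", {
  p <- row70()
  pops <- lapply(c("a", "b", "c"), function(l) truth_populations(p, label = l))
  rad <- make_rad(c("a", "b", "c"), c(0.02, 0.05, 0.09))
  ref <- build_reference(pops, rad)
  expect_setequal(ref$members, c("a", "b", "c"))
  expect_equal(unname(coef(ref$fit)), c(p$dHm, p$Tm, p$dCp), tolerance = 1e-7)
  # symmetric +/- eps perturbations of one member cancel in the average
  eps <- 0.01
  base <- truth_populations(p, label = "a")
  up <- population_series("b", base$temperature, pmin(1, base$f_F + eps))
  dn <- population_series("c", base$temperature, pmax(0, base$f_F - eps))
  ref2 <- build_reference(list(up, dn), make_rad(c("b", "c"), c(0.01, 0.01)))
  expect_equal(unname(coef(ref2$fit)), c(p$dHm, p$Tm, p$dCp), tolerance = 1e-6)
  expect_error(build_reference(pops[1], rad[1, ]), "at least 2")
})

test_that("a reference from noisy members recovers the common generator", {
  gen_p <- thermo_params(25, 300, 2.7)
  pops <- lapply(1:11, function(i) {
    spec <- synthetic_spec(gen_p, noise_sigma = 0.03, seed = 400 + i)
    g <- generate_series(spec, residue_label = paste0("m", i))
    volumes_to_populations(g$volumes, anchor_T = spec$anchor_T,
                           anchor_fraction = spec$anchor_fraction,
                           v_u_rule = "zero")
  })
  rad <- make_rad(paste0("m", 1:11), rep(0.05, 11))
  ref <- build_reference(pops, rad)
  expect_lt(abs(ref$params$Tm - 300), 0.3)
})

test_that("flagged members are excluded and parameter-averaging mode works", {
  p <- row70()
  pops <- lapply(c("a", "b", "c"), function(l) truth_populations(p, label = l))
  fits <- lapply(pops, fit_stability)
  names(fits) <- c("a", "b", "c")
  fits$c$flagged <- TRUE
  rad <- make_rad(c("a", "b", "c"), c(0.02, 0.05, 0.09))
  ref <- build_reference(pops, rad, fits = fits)
  expect_setequal(ref$members, c("a", "b"))
  refp <- build_reference(pops, rad, fits = fits, method = "parameters")
  expect_equal(refp$params$Tm, p$Tm, tolerance = 1e-7)
})

test_that("classification thresholds partition by the mean absolute shift", {
  ref <- row70()  # Tm 298.2, Tc ~283.18
  mk <- function(dTm, dTc) params_from_zeros(ref$Tc + dTc, ref$Tm + dTm, 3.7)
  rec <- classify_residue(mk(-0.5, +1.0), ref)
  expect_equal(rec$mean_abs_dT, 0.75, tolerance = 1e-6)
  expect_equal(rec$category, "consistent")
  rec <- classify_residue(mk(-2, -5), ref)
  expect_equal(rec$mean_abs_dT, 3.5, tolerance = 1e-6)
  expect_equal(rec$category, "outlier")
  rec <- classify_residue(mk(-1.8, -2.6), ref)
  expect_equal(rec$mean_abs_dT, 2.2, tolerance = 1e-6)
  expect_equal(rec$category, "intermediate")
  # swapping the signs of both shifts leaves the category unchanged
  expect_equal(classify_residue(mk(1.8, 2.6), ref)$category, "intermediate")
  expect_equal(classify_residue(mk(2, 5), ref)$category, "outlier")
  expect_error(classify_residue(mk(0, 0), ref, consistent_K = 3, outlier_K = 2))
})

test_that("identical members classify as consistent with zero shift", {
  p <- row70()
  fit <- fit_stability(truth_populations(p, label = "a"))
  rec <- classify_residue(fit, p)
  expect_equal(rec$mean_abs_dT, 0, tolerance = 1e-6)
  expect_equal(rec$category, "consistent")
})

test_that("flagged fits are unclassifiable, never silently categorised", {
  T <- default_grid()
  flat <- fit_stability(population_series("f", T, rep(0.5, length(T))))
  rec <- classify_residue(flat, row70())
  expect_equal(rec$category, "unclassifiable")
  expect_true(is.na(rec$dTm))
})

test_that("pure mechanism variants are labelled I, II, III respectively", {
  ref <- row70()
  cc <- gh_linear_coefs(ref)
  # Mechanism I: lift the whole curve (same dCp, same Ts, higher dHs)
  lift <- gh_from_linear(cc["c0"] + 0.2 * ref$dHs, cc["c1"], cc["dCp"])
  m <- mechanism_decomposition(lift, ref)
  expect_equal(m$labels, "I")
  expect_lt(abs(lift$Ts - ref$Ts), 0.1)
  expect_equal(m$ddHs, 0.2 * ref$dHs, tolerance = 1e-6)
  # Mechanism II: reduce dCp by 30% at unchanged maximum
  dCp2 <- 0.7 * ref$dCp
  c1_2 <- dCp2 * (1 + log(ref$Ts))
  c0_2 <- ref$dHs - dCp2 * ref$Ts
  broad <- gh_from_linear(c0_2, c1_2, dCp2)
  m2 <- mechanism_decomposition(broad, ref)
  expect_equal(m2$labels, "II")
  expect_lt(abs(broad$dHs - ref$dHs) / ref$dHs, 0.01)  # same peak height
  expect_lt(abs(broad$Ts - ref$Ts), 0.1)
  # Mechanism III: translate the whole curve by -5 K (least-squares
  # projection of the shifted curve back onto the Gibbs-Helmholtz family)
  Tg <- seq(ref$Tc - 2, ref$Tm + 2, by = 0.5)
  shifted <- fit_gibbs_helmholtz_dg(Tg - 5, gibbs_helmholtz(Tg, ref))
  m3 <- mechanism_decomposition(shifted, ref)
  expect_true("III" %in% m3$labels)
  expect_lt(m3$dTs, 0)
  expect_equal(m3$dTs, -5, tolerance = 0.05)
  # shape preserved: profiles superimpose after translating back
  diff <- gibbs_helmholtz(Tg - 5, shifted) - gibbs_helmholtz(Tg, ref)
  expect_lt(max(abs(diff)), 0.01 * ref$dHs)
})

test_that("secondary-structure grouping partitions the classified residues", {
  ref <- row70()
  mk <- function(dTm, dTc) params_from_zeros(ref$Tc + dTc, ref$Tm + dTm, 3.7)
  fits <- list(a = mk(0.1, 0.1), b = mk(-2, -5), c = mk(0.2, -0.4),
               d = mk(-4, -6))
  recs <- classify_residues(fits, ref)
  expect_equal(recs$residue_label, c("a", "b", "c", "d"))
  # no annotations: everything is loop
  g0 <- group_by_secondary_structure(recs)
  expect_equal(g0$element, "loop")
  expect_equal(g0$n, 4)
  ss <- data.frame(residue_label = c("a", "b", "c"),
                   element = c("H1", "H1", "S1"))
  g <- group_by_secondary_structure(recs, ss)
  expect_setequal(g$element, c("H1", "S1", "loop"))
  expect_equal(sum(g$n), nrow(recs))
  h1 <- g[g$element == "H1", ]
  expect_equal(h1$n_consistent + h1$n_intermediate + h1$n_outlier +
                 h1$n_unclassifiable, h1$n)
})

test_that("published outliers sit below the buried-core reference curve", {
  tab <- yfh1_thermo_table()
  core <- select_by_rad(tab, 0.1)
  ci <- tab$residue_label %in% core
  ref_Tm <- mean(tab$Tm_K[ci])
  ref_Tc <- mean(tab$Tc_K[ci])
  expect_equal(ref_Tm, 300.3, tolerance = 0.1 / 300.3)
  expect_equal(ref_Tc, 282.4, tolerance = 0.1 / 282.4)
  out <- tab[tab$residue_label %in% yfh1_reported_sets()$ill_behaved, ]
  expect_equal(nrow(out), 21)
  dTm <- out$Tm_K - ref_Tm
  dTc <- out$Tc_K - ref_Tc
  # moderate decrease of Tm, large decrease of Tc
  expect_lt(mean(dTc), mean(dTm))
  expect_lt(mean(dTm), 0)
})
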