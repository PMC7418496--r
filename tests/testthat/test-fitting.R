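test_that("noiseless bi-bi fits recover generating parameters across random draws", {
  set.seed(101)
  for (k in 1:12) {
    p <- draw_params()
    d <- noiseless_grid(p)
    f <- fit_bibi(d, fast_opts)
    expect_true(f$converged)
    for (nm in c("vmax", "ka", "kb", "kia"))
      expect_lt(rel_err(f$estimates[[nm]], p[[nm]]), 1e-4)
  }
})

test_that("noiseless inhibition fits recover every mechanism's parameters", {
  set.seed(202)
  # the two saturation slices identify the slope/intercept mechanisms; the
  # noncompetitive law factorizes as bibi/(1 + I/K), so its bi-bi constants
  # need a crossed substrate grid to pin down
  crossed <- grid_design(a_levels = log_levels_test(0.002, 0.1, 5),
                         b_levels = log_levels_test(0.002, 0.1, 5),
                         i_levels = c(0, 0.01, 0.02, 0.06, 0.12))
  kinds <- c("competitive", "uncompetitive", "noncompetitive", "mixed")
  for (kind in kinds) {
    for (k in 1:3) {
      ki <- exp(runif(2, log(0.01), log(0.2)))
      p <- kinetic_parameters(
        vmax = exp(runif(1, log(0.5), log(10))),
        ka = exp(runif(1, log(0.005), log(0.1))),
        kb = exp(runif(1, log(0.005), log(0.1))),
        kia = exp(runif(1, log(0.005), log(0.1))),
        kis = switch(kind, competitive = ki[1], uncompetitive = NA,
                     noncompetitive = ki[1], mixed = ki[1]),
        kii = switch(kind, competitive = NA, uncompetitive = ki[2],
                     noncompetitive = ki[1], mixed = ki[2]))
      d <- if (kind == "noncompetitive")
        simulate_velocity_grid(p, crossed, noise_model(0, seed = 1))
      else noiseless_slices(p)
      f <- fit_inhibition(d, kind, "full", fit_options(n_starts = 6))
      expect_true(f$converged)
      for (nm in c("vmax", "ka", "kb", "kia", "kis", "kii")) {
        if (is.na(p[[nm]])) next
        expect_lt(rel_err(f$estimates[[nm]], p[[nm]]), 1e-3)
      }
    }
  }
})

test_that("velocity scaling moves vmax only; 1/v^2 weighting keeps Kms under rescaling", {
  d <- noiseless_grid(kl4)
  d2 <- d; d2$v <- 2 * d$v
  f1 <- fit_bibi(d, fast_opts)
  f2 <- fit_bibi(d2, fast_opts)
  expect_equal(f2$estimates$vmax, 2 * f1$estimates$vmax, tolerance = 1e-8)
  for (nm in c("ka", "kb", "kia"))
    expect_equal(f2$estimates[[nm]], f1$estimates[[nm]], tolerance = 1e-8)

  wopts <- fit_options(n_starts = 3, seed = 1, weighting = "inv_v2")
  dn <- simulate_velocity_grid(kl4, default_grid_design("KlLeu4"),
                               noise_model(0.03, seed = 5))
  ds <- dn; ds$v <- 3.7 * dn$v
  g1 <- fit_bibi(dn, wopts)
  g2 <- fit_bibi(ds, wopts)
  for (nm in c("ka", "kb", "kia"))
    expect_equal(g2$estimates[[nm]], g1$estimates[[nm]], tolerance = 1e-8)
})

test_that("estimates are invariant to observation order", {
  d <- simulate_velocity_grid(kl4, default_inhibition_design(),
                              noise_model(0.03, seed = 9))
  f1 <- fit_inhibition(d, "mixed", "full", fast_opts)
  set.seed(1)
  dp <- d[sample(nrow(d)), ]
  f2 <- fit_inhibition(dp, "mixed", "full", fast_opts)
  for (nm in c("vmax", "ka", "kb", "kia", "kis", "kii"))
    expect_lt(rel_err(f2$estimates[[nm]], f1$estimates[[nm]]), 1e-10)
})

test_that("a saturating-B Michaelis surface drives kb to the boundary flag", {
  p0 <- kinetic_parameters(vmax = 3.9, ka = 0.026, kb = 2e-8, kia = 0.017)
  d <- noiseless_grid(p0)
  f <- fit_bibi(d, fast_opts)
  expect_true(f$boundary[["kb"]])
  expect_false(any(f$boundary[c("ka", "kia")]))
})

test_that("design errors are rejected with informative messages", {
  d <- noiseless_grid(kl4)
  di <- noiseless_slices(kl4)
  expect_error(fit_bibi(di), "inhibitor-free")
  one_a <- d[d$a == d$a[1], ]
  expect_error(fit_bibi(one_a), "both substrates")
  expect_error(fit_bibi(d[c(1, 2, 9, 10), ]), "under-determined")
  expect_error(fit_inhibition(d, "mixed"), "leucine levels")
})

test_that("fit reports carry a coherent uncertainty contract", {
  d <- simulate_velocity_grid(kl4, default_inhibition_design(),
                              noise_model(0.03, seed = 13))
  f <- fit_inhibition(d, "mixed", "full", fast_opts)
  se <- f$standard_errors[c("vmax", "ka", "kb", "kia", "kis", "kii")]
  expect_true(all(se > 0))
  expect_equal(unname(sqrt(diag(f$covariance))),
               unname(f$standard_errors[colnames(f$covariance)]),
               tolerance = 1e-10)
  expect_true(isSymmetric(f$covariance, tol = 1e-10))
  expect_gte(f$rss, 0)
  expect_identical(f$n_obs, nrow(d))
})

test_that("mixed fits on kis == kii data return nearly equal constants", {
  pn <- kinetic_parameters(vmax = 3.864, ka = 0.026, kb = 0.025,
                           kia = 0.017, kis = 0.05, kii = 0.05)
  d <- simulate_velocity_grid(pn, default_inhibition_design(),
                              noise_model(0.02, seed = 4))
  f <- fit_inhibition(d, "mixed", "full", fit_options(n_starts = 5))
  z <- abs(f$estimates$kis - f$estimates$kii) /
    sqrt(f$standard_errors[["kis"]]^2 + f$standard_errors[["kii"]]^2)
  expect_lt(z, 2.5)
})

test_that("model comparison identifies generating mechanisms sensibly", {
  d <- simulate_velocity_grid(kl4, default_inhibition_design(),
                              noise_model(0.03, seed = 21))
  mc <- compare_inhibition_models(d, fast_opts)
  expect_s3_class(mc, "model_comparison")
  expect_identical(mc$best, "mixed")
  expect_identical(mc$table$model[which.min(mc$table$aicc)],
                   mc$table$model[1])
  # competitive truth: never diagnosed as uncompetitive
  pc <- kinetic_parameters(vmax = 3.864, ka = 0.026, kb = 0.025,
                           kia = 0.017, kis = 0.034)
  for (s in 1:5) {
    dc <- simulate_velocity_grid(pc, default_inhibition_design(),
                                 noise_model(0.03, seed = s))
    best <- compare_inhibition_models(dc, fast_opts)$best
    expect_true(best %in% c("competitive", "mixed"))
  }
  expect_error(compare_inhibition_models(noiseless_grid(kl4), fast_opts),
               "leucine levels")
})

test_that("IC50 fits recover generating values and police identifiability", {
  lv <- c(0, 0.005, 0.01, 0.02, 0.04, 0.08, 0.16)
  for (truth in c(0.020, 0.037)) {
    dr <- data.frame(i = lv, relative_activity = 1 / (1 + lv / truth))
    f <- estimate_ic50(dr)
    expect_lt(rel_err(f$ic50, truth), 1e-6)
    expect_identical(f$model_form, "hyperbolic")
    expect_identical(f$hill_slope, 1)
    expect_false(f$extrapolated)
  }
  # Hill option recovers a steeper generating slope
  drh <- data.frame(i = lv, relative_activity = 1 / (1 + (lv / 0.03)^2))
  fh <- estimate_ic50(drh, hill = TRUE)
  expect_lt(rel_err(fh$ic50, 0.03), 1e-4)
  expect_lt(rel_err(fh$hill_slope, 2), 1e-4)
  expect_error(estimate_ic50(data.frame(i = lv, relative_activity = rep(1, 7))),
               "unidentifiable")
  expect_error(
    estimate_ic50(data.frame(i = lv, relative_activity = 0.4 / (1 + lv))),
    "unidentifiable")
  expect_error(estimate_ic50(data.frame(i = c(0, 0.01, 0.02),
                                        relative_activity = c(1, 0.6, 0.4))),
               "4 distinct")
})

test_that("double-reciprocal replots separate the inhibition mechanisms", {
  d <- noiseless_slices(kl4)
  lw <- lineweaver_points(d[d$b == 0.25, ], varied = "a")
  expect_true(all(diff(lw$lines$slope) > 0))
  expect_true(all(diff(lw$lines$intercept) > 0))
  expect_true(all(lw$lines$r_squared > 1 - 1e-10))
  # slope ratio against the closed-form replot algebra (slope factor 1+I/kis)
  s0 <- lw$lines$slope[lw$lines$i == 0]
  s6 <- lw$lines$slope[lw$lines$i == 0.06]
  expect_equal(s6 / s0, 1 + 0.06 / 0.034, tolerance = 1e-8)
  # competitive: intercepts constant across leucine
  pc <- kinetic_parameters(vmax = 3.864, ka = 0.026, kb = 0.025,
                           kia = 0.017, kis = 0.034)
  dc <- noiseless_slices(pc)
  lwc <- lineweaver_points(dc[dc$b == 0.25, ], varied = "a")
  expect_lt(diff(range(lwc$lines$intercept)), 1e-10)
  # zero velocities are excluded with a warning
  dz <- as.data.frame(d[d$b == 0.25, ])
  dz$v[1] <- 0
  expect_warning(lwz <- lineweaver_points(dz, varied = "a"), "excluded")
  expect_identical(lwz$n_excluded, 1L)
})
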