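test_that("initial-rate windows land on the linear phase", {
  # exact linear trace: recovered exactly, earliest window
  tr <- simulate_trace(0.02, duration_s = 600)
  r <- estimate_initial_rate(tr)
  expect_equal(r$dA412_per_min, 0.02, tolerance = 1e-12)
  expect_identical(r$window, c(0, 60))
  expect_false(r$low_quality)

  # contaminant-CoA burst, known extract-addition time
  trb <- simulate_trace(0.02, 900, burst = list(amplitude = 0.3, tau_s = 45))
  rb <- estimate_initial_rate(trb, assay_conditions(preincubation_s = 300))
  expect_lt(rel_err(rb$dA412_per_min, 0.02), 0.02)

  # same trace, automatic burst detection plus the curvature gate
  ra <- estimate_initial_rate(trb)
  expect_lt(rel_err(ra$dA412_per_min, 0.02), 0.03)

  # noisy linear phase: within 10% of the generating slope
  trn <- simulate_trace(0.02, 600, noise_sd = 0.002, seed = 7)
  rn <- estimate_initial_rate(trn)
  expect_lt(rel_err(rn$dA412_per_min, 0.02), 0.10)

  # blank (no enzyme): slope statistically indistinguishable from zero
  flat <- simulate_trace(0, 600, noise_sd = 0.002, seed = 3)
  rf <- estimate_initial_rate(flat)
  expect_lt(abs(rf$dA412_per_min), 2 * rf$slope_se)
  expect_true(rf$low_quality)
})

test_that("rate estimation is invariant to baseline shifts and guards inputs", {
  tr <- simulate_trace(0.02, 600, noise_sd = 0.001, seed = 5)
  shifted <- absorbance_trace(tr$time, tr$a412 + 0.42)
  r1 <- estimate_initial_rate(tr)
  r2 <- estimate_initial_rate(shifted)
  expect_equal(r1$dA412_per_min, r2$dA412_per_min, tolerance = 1e-10)
  expect_identical(r1$window, r2$window)

  expect_error(absorbance_trace(1:5, rnorm(5)), ">= 10 points")
  expect_error(absorbance_trace(c(1:9, 9), rnorm(10)), "increasing")
  short <- absorbance_trace(seq(0, 20, 2), rep(0.05, 11))
  expect_error(estimate_initial_rate(short,
                                     assay_conditions(preincubation_s = 0)),
               "beyond the preincubation")
})

test_that("specific-activity conversion follows the Beer-Lambert unit audit", {
  cond <- assay_conditions(epsilon = 14.15, path_cm = 1, volume_ml = 1,
                           protein_mg = 0.5)
  sa <- to_specific_activity(0.1415, cond)
  # unit-by-unit oracle: 0.1415 A/min / 14.15 mM^-1 cm^-1 = 0.01 mM/min
  # = 10 nmol/min in 1 mL, / 0.5 mg = 20
  expect_equal(sa$value, 20, tolerance = 1e-12)
  audit <- attr(sa, "conversion")
  expect_equal(unname(audit["mM_per_min"]), 0.01, tolerance = 1e-12)
  expect_equal(unname(audit["nmol_per_min"]), 10, tolerance = 1e-12)

  expect_equal(to_specific_activity(0, cond)$value, 0)
  # linear in rate; inversely linear in protein and in epsilon
  expect_equal(to_specific_activity(0.283, cond)$value, 40, tolerance = 1e-12)
  cond2 <- assay_conditions(protein_mg = 1)
  expect_equal(to_specific_activity(0.1415, cond2)$value, 10,
               tolerance = 1e-12)
  cond3 <- assay_conditions(epsilon = 28.3, protein_mg = 0.5)
  expect_equal(to_specific_activity(0.1415, cond3)$value, 10,
               tolerance = 1e-12)
  expect_error(to_specific_activity(0.1, assay_conditions(protein_mg = 0)),
               "protein_mg")
})

test_that("relative activity normalization maps the reference to 1", {
  df <- data.frame(i = c(0, 0.02), specific_activity = c(20, 10))
  out <- relative_activity_series(df)
  expect_equal(out$relative_activity, c(1, 0.5))
  mono <- data.frame(i = c(0, 0.01, 0.05, 0.2),
                     specific_activity = c(18, 14, 8, 3))
  rel <- relative_activity_series(mono)
  expect_true(all(diff(rel$relative_activity) < 0))
  expect_error(relative_activity_series(
    data.frame(i = c(0.01, 0.02), specific_activity = c(5, 3))),
    "reference level")
  expect_error(relative_activity_series(
    data.frame(i = c(0, 0.02), specific_activity = c(0, 3))),
    "not positive")
})

test_that("hyperbolic activities round-trip through normalization to the IC50", {
  lv <- c(0, 0.005, 0.01, 0.02, 0.04, 0.08, 0.16)
  acts <- 20 / (1 + lv / 0.037)
  rel <- relative_activity_series(data.frame(i = lv,
                                             specific_activity = acts))
  f <- estimate_ic50(rel)
  expect_lt(rel_err(f$ic50, 0.037), 1e-6)
})

test_that("trace -> rate -> activity -> IC50 pipeline recovers the truth within 15%", {
  ic50_true <- 0.037
  lv <- c(0, 0.005, 0.01, 0.02, 0.04, 0.08, 0.16)
  cond <- assay_conditions(preincubation_s = 300, protein_mg = 0.5)
  acts <- vapply(seq_along(lv), function(k) {
    rate <- 0.12 / (1 + lv[k] / ic50_true)
    tr <- simulate_trace(rate, 900, burst = list(amplitude = 0.2, tau_s = 45),
                         noise_sd = 0.001, seed = 100 + k)
    to_specific_activity(estimate_initial_rate(tr, cond), cond)$value
  }, numeric(1))
  rel <- relative_activity_series(data.frame(i = lv,
                                             specific_activity = acts))
  f <- estimate_ic50(rel)
  expect_lt(rel_err(f$ic50, ic50_true), 0.15)
})
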