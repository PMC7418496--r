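test_that("rate_bibi matches direct arithmetic evaluation and limits", {
  # independent oracle: the denominator assembled term by term
  denom <- 0.017 * 0.025 + 0.025 * 0.1 + 0.026 * 0.08 + 0.1 * 0.08
  expect_equal(denom, 0.013005, tolerance = 1e-12)
  expect_equal(rate_bibi(kl4, a = 0.1, b = 0.08),
               3.864 * 0.1 * 0.08 / denom, tolerance = 1e-12)
  expect_equal(rate_bibi(kl4, a = 0.1, b = 0.08), 2.376932,
               tolerance = 1e-6)
  # zero-substrate and saturation limits
  expect_identical(rate_bibi(kl4, a = 0, b = 0.05), 0)
  expect_identical(rate_bibi(kl4, a = 0.05, b = 0), 0)
  expect_equal(rate_bibi(kl4, a = 1e6 * kl4$ka, b = 1e6 * kl4$kb),
               kl4$vmax, tolerance = 1e-5)
  expect_error(rate_bibi(kl4, a = -0.1, b = 0.05), "nonnegative")
  expect_error(rate_bibi(kl4, a = NaN, b = 0.05), "finite")
})

test_that("rate_inhibited reproduces the assay-condition inhibition ratio", {
  # oracle: slope term P and intercept term Q assembled by hand
  p_term <- 0.017 * 0.025 + 0.026 * 10
  q_term <- 0.025 * 0.25 + 0.25 * 10
  v0 <- 3.864 * 0.25 * 10 / (p_term + q_term)
  vi <- 3.864 * 0.25 * 10 /
    (p_term * (1 + 0.073 / 0.034) + q_term * (1 + 0.073 / 0.073))
  expect_equal(rate_inhibited(kl4, 0.25, 10, 0.073), vi, tolerance = 1e-12)
  expect_equal(rate_inhibited(kl4, 0.25, 10, 0.073) /
                 rate_inhibited(kl4, 0.25, 10, 0), vi / v0,
               tolerance = 1e-12)
  expect_equal(vi / v0, 0.474390, tolerance = 1e-5)
  expect_error(rate_inhibited(kl4, 0.1, 0.1, -0.01), "nonnegative")
})

test_that("inhibited laws reduce to the bi-bi law at zero inhibitor", {
  set.seed(42)
  for (k in 1:25) {
    p <- draw_params(with_inhibition = TRUE)
    a <- exp(runif(1, log(1e-3), log(1))); b <- exp(runif(1, log(1e-3), log(1)))
    v0 <- rate_bibi(p, a, b)
    expect_identical(rate_inhibited(p, a, b, 0), v0)
    expect_equal(rate_apparent_varied_a(p, a, b, 0), v0, tolerance = 1e-14)
    expect_equal(rate_apparent_varied_b(p, a, b, 0), v0, tolerance = 1e-14)
  }
})

test_that("acetyl-CoA-varied apparent form is algebraically the full law", {
  set.seed(7)
  for (k in 1:25) {
    p <- draw_params(with_inhibition = TRUE)
    a <- exp(runif(5, log(1e-3), log(1)))
    b <- exp(runif(5, log(1e-3), log(1)))
    i <- runif(5, 0, 0.2)
    expect_equal(rate_apparent_varied_a(p, a, b, i),
                 rate_inhibited(p, a, b, i), tolerance = 1e-12)
  }
  expect_error(rate_apparent_varied_a(kl4, 0.05, 0, 0.02), "positive")
  expect_error(rate_apparent_varied_b(kl4, 0, 0.05, 0.02), "positive")
})

test_that("alpha-KIV-varied apparent form matches its hand-expanded denominator", {
  # oracle: term-by-term expansion with plain arithmetic
  d1 <- 0.025 * (1 + 0.017 / 0.1) * (1 + 0.06 / 0.034)
  d2 <- 0.05 * (1 + 0.026 / 0.1) * (1 + 0.06 / 0.073)
  v_oracle <- 3.864 * 0.05 / (d1 + d2)
  expect_equal(rate_apparent_varied_b(kl4, a = 0.1, b = 0.05, i = 0.06),
               v_oracle, tolerance = 1e-12)
  expect_equal(v_oracle, 0.9874851, tolerance = 1e-6)
  # it differs from the full law under inhibition (different term grouping)
  expect_gt(abs(rate_apparent_varied_b(kl4, 0.1, 0.05, 0.06) -
                rate_inhibited(kl4, 0.1, 0.05, 0.06)), 1e-4)
})

test_that("rates are monotone in substrates (up) and inhibitor (down)", {
  set.seed(11)
  for (k in 1:20) {
    p <- draw_params(with_inhibition = TRUE)
    a <- sort(exp(runif(6, log(1e-3), log(1))))
    b0 <- exp(runif(1, log(1e-3), log(1)))
    expect_true(all(diff(rate_bibi(p, a, b0)) > 0))
    expect_true(all(diff(rate_bibi(p, b0, sort(a))) > 0))
    i <- sort(runif(6, 0, 0.3))
    expect_true(all(diff(rate_inhibited(p, 0.05, 0.05, i)) < 0))
  }
})

test_that("saturating both substrates leaves only the intercept factor", {
  for (i in c(0, 0.02, 0.1)) {
    v <- rate_inhibited(kl4, 1e6 * kl4$ka, 1e6 * kl4$kb, i)
    expect_lt(abs(v - kl4$vmax / (1 + i / kl4$kii)) / kl4$vmax, 1e-4)
  }
  # competitive inhibition is outcompeted by saturating acetyl-CoA
  pc <- kinetic_parameters(vmax = 2, ka = 0.02, kb = 0.03, kia = 0.015,
                           kis = 0.04)
  expect_equal(rate_inhibited(pc, 1e7, 0.05, 0.12),
               rate_inhibited(pc, 1e7, 0.05, 0), tolerance = 1e-5)
})

test_that("predicted_ic50 halves the rate and scales with the constants", {
  ic50 <- predicted_ic50(kl4, a = 0.25, b = 10)
  expect_equal(ic50, 0.0658862, tolerance = 1e-5)
  expect_equal(rate_inhibited(kl4, 0.25, 10, ic50),
               rate_inhibited(kl4, 0.25, 10, 0) / 2, tolerance = 1e-10)
  # independent cross-check: bisection on the rate law itself
  half <- rate_inhibited(kl4, 0.25, 10, 0) / 2
  root <- uniroot(function(i) rate_inhibited(kl4, 0.25, 10, i) - half,
                  c(1e-6, 10), tol = 1e-12)$root
  expect_equal(ic50, root, tolerance = 1e-8)
  # noncompetitive: IC50 equals the shared constant at any conditions
  pn <- kinetic_parameters(vmax = 1, ka = 0.02, kb = 0.03, kia = 0.01,
                           kis = 0.05, kii = 0.05)
  expect_equal(predicted_ic50(pn, 0.01, 0.02), 0.05, tolerance = 1e-12)
  expect_equal(predicted_ic50(pn, 5, 7), 0.05, tolerance = 1e-12)
  # doubling both constants doubles the IC50
  p2 <- kinetic_parameters(vmax = kl4$vmax, ka = kl4$ka, kb = kl4$kb,
                           kia = kl4$kia, kis = 2 * kl4$kis,
                           kii = 2 * kl4$kii)
  expect_equal(predicted_ic50(p2, 0.25, 10), 2 * ic50, tolerance = 1e-12)
  p_none <- kinetic_parameters(vmax = 1, ka = 0.02, kb = 0.03, kia = 0.01)
  expect_error(predicted_ic50(p_none, 0.25, 10), "no inhibition")
})

test_that("parameter container enforces positivity and kind consistency", {
  expect_error(kinetic_parameters(vmax = -1, ka = 0.02, kb = 0.03,
                                  kia = 0.01), "positive")
  expect_error(kinetic_parameters(vmax = 1, ka = 0.02, kb = 0.03,
                                  kia = 0.01, kis = 0), "positive")
  p <- kinetic_parameters(vmax = 1, ka = 0.02, kb = 0.04, kia = 0.01,
                          kis = 0.05)
  expect_equal(kib(p), 0.01 * 0.04 / 0.02, tolerance = 1e-15)
  expect_silent(check_inhibition_kind(p, "competitive"))
  expect_error(check_inhibition_kind(p, "mixed"), "inconsistent")
  expect_error(check_inhibition_kind(p, "uncompetitive"), "inconsistent")
})
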