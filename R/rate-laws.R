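#' Steady-state ordered bi-bi rate law
#'
#' Initial velocity of a compulsory-ordered two-substrate reaction in which
#' acetyl-CoA (A) binds first and alpha-ketoisovalerate (B) second:
#'
#' \deqn{v = \frac{V_{max} A B}{K_{ia} K_b + K_b A + K_a B + A B}}
#'
#' Vectorized over `a` and `b` (recycled to common length).
#'
#' @param params A [kinetic_parameters()] object (`vmax`, `ka`, `kb`, `kia`
#'   used; inhibition constants ignored).
#' @param a Acetyl-CoA concentration(s), mM, nonnegative.
#' @param b Alpha-ketoisovalerate concentration(s), mM, nonnegative.
#' @return Velocity in the units of `params$vmax`; exactly 0 where `a == 0`
#'   or `b == 0`.
#' @examples
#' p <- klleu4_parameters()
#' rate_bibi(p, a = 0.1, b = 0.08)
#' @export
rate_bibi <- function(params, a, b) {
  stopifnot(inherits(params, "kinetic_parameters"))
  check_conc(a, "a"); check_conc(b, "b")
  # grouped as in the inhibited law so the i = 0 reduction is bit-exact
  with(params, vmax * a * b / ((kia * kb + ka * b) + (kb * a + a * b)))
}

check_conc <- function(x, name, allow_zero = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  if (any(x < 0) || (!allow_zero && any(x == 0)))
    stop(sprintf("'%s' must be %s", name,
                 if (allow_zero) "nonnegative" else "strictly positive"),
         call. = FALSE)
  invisible(x)
}

# Inhibition factors (1 + I/K); an absent constant contributes exactly 1,
# i.e. behaves as K = +Inf.
inhib_factor <- function(i, k) {
  if (is.na(k)) rep(1, length(i)) else 1 + i / k
}

#' Ordered bi-bi rate law under mixed leucine inhibition (full form)
#'
#' The package's single internally consistent two-substrate inhibited law:
#' the slope-associated constant `kis` scales the substrate-independent and
#' `ka*B` denominator terms, the intercept-associated constant `kii` scales
#' the terms carrying A:
#'
#' \deqn{v = \frac{V_{max} A B}{(K_{ia} K_b + K_a B)(1 + I/K_{is}) +
#'       (K_b A + A B)(1 + I/K_{ii})}}
#'
#' At `i = 0` this is exactly [rate_bibi()].  An absent (`NA`) inhibition
#' constant contributes a factor of exactly 1 (competitive: `kii` absent;
#' uncompetitive: `kis` absent).
#'
#' @inheritParams rate_bibi
#' @param i Leucine concentration(s), mM, nonnegative.
#' @return Velocity; strictly decreasing in `i` whenever either constant is
#'   finite and `a`, `b` are positive.
#' @examples
#' p <- klleu4_parameters()
#' rate_inhibited(p, a = 0.25, b = 10, i = 0.073) /
#'   rate_inhibited(p, a = 0.25, b = 10, i = 0)
#' @export
rate_inhibited <- function(params, a, b, i = 0) {
  stopifnot(inherits(params, "kinetic_parameters"))
  check_conc(a, "a"); check_conc(b, "b"); check_conc(i, "i")
  n <- max(length(a), length(b), length(i))
  a <- rep_len(a, n); b <- rep_len(b, n); i <- rep_len(i, n)
  with(params,
    vmax * a * b / ((kia * kb + ka * b) * inhib_factor(i, kis) +
                    (kb * a + a * b)   * inhib_factor(i, kii)))
}

#' Apparent inhibited rate law with acetyl-CoA as the varied substrate
#'
#' The replot form used when acetyl-CoA is varied at fixed alpha-KIV:
#'
#' \deqn{v = \frac{V_{max} A}{K_a (1 + K_{ib}/B)(1 + I/K_{is}) +
#'       A (1 + K_b/B)(1 + I/K_{ii})}}
#'
#' with `Kib = kia*kb/ka` (see [kib()]).  Algebraically identical to
#' [rate_inhibited()] for all inputs; exposed separately because fitting of
#' acetyl-CoA-varied saturation slices is conventionally written in this
#' form.
#'
#' @inheritParams rate_inhibited
#' @return Velocity; requires `b > 0`.
#' @export
rate_apparent_varied_a <- function(params, a, b, i = 0) {
  stopifnot(inherits(params, "kinetic_parameters"))
  check_conc(a, "a"); check_conc(b, "b", allow_zero = FALSE)
  check_conc(i, "i")
  n <- max(length(a), length(b), length(i))
  a <- rep_len(a, n); b <- rep_len(b, n); i <- rep_len(i, n)
  kib_v <- kib(params)
  with(params,
    vmax * a / (ka * (1 + kib_v / b) * inhib_factor(i, kis) +
                a * (1 + kb / b) * inhib_factor(i, kii)))
}

#' Apparent inhibited rate law with alpha-KIV as the varied substrate
#'
#' The replot form used when alpha-KIV is varied at fixed acetyl-CoA:
#'
#' \deqn{v = \frac{V_{max} B}{K_b (1 + K_{ia}/A)(1 + I/K_{is}) +
#'       B (1 + K_a/A)(1 + I/K_{ii})}}
#'
#' At `i = 0` this equals [rate_bibi()]; at `i > 0` it groups the `kb*A`
#' denominator term with the slope factor (and `ka*B` with the intercept
#' factor), the opposite of [rate_inhibited()].  Both groupings are
#' classical apparent forms; the package keeps [rate_inhibited()] as the
#' single generating law and offers this form for fitting alpha-KIV-varied
#' slices in its conventional parameterization.
#'
#' @inheritParams rate_inhibited
#' @return Velocity; requires `a > 0`.
#' @export
rate_apparent_varied_b <- function(params, a, b, i = 0) {
  stopifnot(inherits(params, "kinetic_parameters"))
  check_conc(a, "a", allow_zero = FALSE); check_conc(b, "b")
  check_conc(i, "i")
  n <- max(length(a), length(b), length(i))
  a <- rep_len(a, n); b <- rep_len(b, n); i <- rep_len(i, n)
  with(params,
    vmax * b / (kb * (1 + kia / a) * inhib_factor(i, kis) +
                b * (1 + ka / a) * inhib_factor(i, kii)))
}

#' Closed-form IC50 implied by the mixed-inhibition rate law
#'
#' The leucine concentration at which [rate_inhibited()] equals half its
#' uninhibited value at fixed substrate concentrations.  Writing
#' `P = kia*kb + ka*b` and `Q = kb*a + a*b`, the denominator is linear in I
#' and
#'
#' \deqn{IC_{50} = \frac{P + Q}{P/K_{is} + Q/K_{ii}}}
#'
#' (absent constants contribute 0 to the denominator sum).  Unlike the
#' inhibition constants, the IC50 depends on the assay concentrations.
#'
#' @param params A [kinetic_parameters()] object with at least one finite
#'   inhibition constant.
#' @param a Acetyl-CoA concentration, mM (> 0).
#' @param b Alpha-KIV concentration, mM (> 0).
#' @return IC50 in mM.
#' @examples
#' predicted_ic50(klleu4_parameters(), a = 0.25, b = 10)
#' @export
predicted_ic50 <- function(params, a, b) {
  stopifnot(inherits(params, "kinetic_parameters"))
  check_conc(a, "a", allow_zero = FALSE)
  check_conc(b, "b", allow_zero = FALSE)
  if (is.na(params$kis) && is.na(params$kii))
    stop("no inhibition: both kis and kii are absent, IC50 is undefined",
         call. = FALSE)
  p_term <- params$kia * params$kb + params$ka * b
  q_term <- params$kb * a + a * b
  denom <- (if (is.na(params$kis)) 0 else p_term / params$kis) +
           (if (is.na(params$kii)) 0 else q_term / params$kii)
  (p_term + q_term) / denom
}
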