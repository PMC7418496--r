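#' Estimate an IC50 from a relative-activity dose-response table
#'
#' Least-squares fit of the one-site inhibition curve
#' `rel(I) = 1 / (1 + (I / IC50)^h)` to relative activities.  The Hill
#' slope `h` is fixed at 1 (rectangular hyperbola) unless `hill = TRUE`;
#' the IC50 (and `h`, when free) is optimized on the log scale.
#'
#' The IC50 is identifiable only if the observed activities bracket 0.5;
#' a table entirely above or entirely below half-maximal activity raises an
#' error rather than returning an extrapolation.
#'
#' @param dose_response Data frame with columns `i` (leucine, mM; the CSV
#'   reader maps `leucine_mM`) and `relative_activity` (1 at `i = 0`).
#' @param hill If `TRUE`, also fit the Hill slope.
#' @param options A [fit_options()] object (weighting ignored; fits are
#'   unweighted).
#' @return An object of class `ic50_fit`: `ic50` (mM), `standard_error`,
#'   `model_form` (`"hyperbolic"` or `"hill"`), `hill_slope`, `rss`,
#'   `converged`, `extrapolated` (TRUE if the estimate falls outside the
#'   tested positive concentration range).
#' @examples
#' dr <- simulate_dose_response(0.020)
#' estimate_ic50(dr)
#' @export
estimate_ic50 <- function(dose_response, hill = FALSE,
                          options = fit_options()) {
  dr <- as.data.frame(dose_response)
  if (!is.null(dr$leucine_mM) && is.null(dr$i)) dr$i <- dr$leucine_mM
  if (!all(c("i", "relative_activity") %in% names(dr)))
    stop("dose_response needs columns i and relative_activity", call. = FALSE)
  check_conc(dr$i, "i")
  if (length(unique(dr$i)) < 4)
    stop("need >= 4 distinct leucine levels", call. = FALSE)
  rel <- dr$relative_activity
  if (all(rel > 0.5) || all(rel < 0.5))
    stop("unidentifiable IC50: activities do not bracket half-maximal ",
         "(all ", if (all(rel > 0.5)) "> 0.5" else "< 0.5", ")",
         call. = FALSE)

  # start: log-linear interpolation of the half-activity crossing
  pos <- dr$i > 0
  start_ic50 <- {
    o <- order(dr$i)
    ii <- dr$i[o]; rr <- rel[o]
    cross <- which(rr <= 0.5 & ii > 0)[1]
    if (is.na(cross)) stats::median(ii[pos]) else ii[cross]
  }
  par0 <- if (hill) c(log_ic50 = log(start_ic50), log_h = 0)
          else c(log_ic50 = log(start_ic50))
  resid_fn <- function(p) {
    ic50 <- exp(p[["log_ic50"]])
    h <- if (hill) exp(p[["log_h"]]) else 1
    rel - 1 / (1 + (dr$i / ic50)^h)
  }
  res <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = options$maxiter,
                              ftol = 1e-13, ptol = 1e-13, gtol = 1e-13))
  ic50 <- exp(res$par[["log_ic50"]])
  h <- if (hill) exp(res$par[["log_h"]]) else 1
  rss <- sum(res$fvec^2)

  # Gauss-Newton SE on the natural scale
  n <- nrow(dr); p <- length(par0)
  hs <- 1e-6
  J <- vapply(seq_len(p), function(k) {
    up <- res$par; up[k] <- up[k] + hs
    dn <- res$par; dn[k] <- dn[k] - hs
    (resid_fn(up) - resid_fn(dn)) / (2 * hs)
  }, numeric(n))
  sigma2 <- if (n > p) rss / (n - p) else 0
  se_log <- tryCatch(sqrt(diag(sigma2 * solve(crossprod(J)))),
                     error = function(e) rep(NA_real_, p))
  structure(list(ic50 = ic50, standard_error = ic50 * se_log[1],
                 model_form = if (hill) "hill" else "hyperbolic",
                 hill_slope = h, rss = rss, n_obs = n,
                 converged = res$info %in% 1:4,
                 extrapolated = ic50 < min(dr$i[pos]) || ic50 > max(dr$i)),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, digits = 4, ...) {
  cat(sprintf("IC50 fit (%s): %s mM +/- %s | hill = %s | rss = %s%s\n",
              x$model_form, format(x$ic50, digits = digits),
              format(x$standard_error, digits = digits),
              format(x$hill_slope, digits = digits),
              format(x$rss, digits = digits),
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}
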