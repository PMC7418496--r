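#' Options controlling nonlinear least-squares fits
#'
#' All kinetic fits optimize in log-parameter space (every constant is
#' physically positive and the plausible values span decades), with
#' Levenberg-Marquardt refinement from multiple starting points: one
#' heuristic start derived from the data plus log-uniform jitter of up to
#' `jitter_decades` decades on each constant.  The best residual sum of
#' squares wins.  Deterministic given `seed`.
#'
#' @param n_starts Number of starting points (first one is the heuristic).
#' @param seed Seed for the start-point jitter.
#' @param weighting `"none"` (ordinary least squares, the default of the
#'   commercial packages this workflow mirrors) or `"inv_v2"` (weights
#'   1/v^2, constant relative error).
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param jitter_decades Half-width of the log10-uniform jitter.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(n_starts = 10L, seed = 1L,
                        weighting = c("none", "inv_v2"),
                        maxiter = 500L, jitter_decades = 1) {
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 weighting = match.arg(weighting),
                 maxiter = as.integer(maxiter),
                 jitter_decades = jitter_decades),
            class = "fit_options")
}

# Full-parameter rate evaluation used inside optimizers.  `th` is a named
# numeric vector with vmax, ka, kb, kia and optionally kis, kii (NA =
# absent).  `law` selects the algebraic form; "full" and "varied_a" are the
# same function of the parameters, "varied_b" groups the kb*a term with the
# slope factor instead.
eval_law <- function(th, a, b, i, law) {
  kis <- th[["kis"]]; kii <- th[["kii"]]
  fs <- if (is.na(kis)) 1 else 1 + i / kis
  fi <- if (is.na(kii)) 1 else 1 + i / kii
  vmax <- th[["vmax"]]; ka <- th[["ka"]]; kb <- th[["kb"]]; kia <- th[["kia"]]
  switch(law,
    bibi     = vmax * a * b / (kia * kb + kb * a + ka * b + a * b),
    full     = ,
    varied_a = vmax * a * b / ((kia * kb + ka * b) * fs + (kb * a + a * b) * fi),
    varied_b = vmax * a * b / ((kia * kb + kb * a) * fs + (ka * b + a * b) * fi),
    stop("unknown law: ", law))
}

free_param_names <- function(model) {
  base <- c("vmax", "ka", "kb", "kia")
  switch(model,
    bibi           = base,
    competitive    = c(base, "kis"),
    uncompetitive  = c(base, "kii"),
    noncompetitive = c(base, "ki"),
    mixed          = c(base, "kis", "kii"),
    stop("unknown model: ", model))
}

# Expand a free-parameter vector (possibly with the shared noncompetitive
# constant "ki") into the full named vector eval_law() expects.
expand_free <- function(free) {
  th <- c(vmax = free[["vmax"]], ka = free[["ka"]], kb = free[["kb"]],
          kia = free[["kia"]], kis = NA_real_, kii = NA_real_)
  if ("ki" %in% names(free)) th[c("kis", "kii")] <- free[["ki"]]
  if ("kis" %in% names(free)) th[["kis"]] <- free[["kis"]]
  if ("kii" %in% names(free)) th[["kii"]] <- free[["kii"]]
  th
}

# Data-driven heuristic start: vmax from the largest observed velocity, each
# Km from the varied-substrate level whose mean response is nearest
# half-maximal, kia = ka, inhibition constants at half the largest inhibitor
# level.
heuristic_start <- function(data, free_names) {
  vmax0 <- 1.2 * max(data$v)
  half_level <- function(s, v) {
    lv <- sort(unique(s))
    if (length(lv) < 2) return(stats::median(lv))
    m <- vapply(lv, function(x) mean(v[s == x]), numeric(1))
    lv[which.min(abs(m - max(data$v) / 2))]
  }
  st <- c(vmax = vmax0,
          ka = half_level(data$a, data$v),
          kb = half_level(data$b, data$v))
  st["kia"] <- st[["ka"]]
  imax <- if (any(data$i > 0)) max(data$i) else 0.1
  st <- c(st, kis = imax / 2, kii = imax / 2, ki = imax / 2)
  st[free_names]
}

build_starts <- function(data, free_names, options, extra_starts = NULL) {
  h <- log(heuristic_start(data, free_names))
  p <- length(h)
  starts <- list(h)
  if (options$n_starts > 1) {
    jit <- with_seed(options$seed,
      matrix(stats::runif((options$n_starts - 1) * p,
                          -options$jitter_decades, options$jitter_decades),
             ncol = p))
    for (r in seq_len(nrow(jit)))
      starts[[r + 1]] <- h + jit[r, ] * log(10)
  }
  for (ex in extra_starts) {
    ex <- ex[free_names]
    if (all(is.finite(ex)) && all(ex > 0)) starts[[length(starts) + 1]] <- log(ex)
  }
  starts
}

fit_weights <- function(data, weighting) {
  if (weighting == "inv_v2") {
    if (any(data$v <= 0))
      stop("1/v^2 weighting requires strictly positive velocities",
           call. = FALSE)
    1 / data$v^2
  } else rep(1, nrow(data))
}

# Canonical observation order: makes every estimate invariant to the order
# in which observations arrive.
canonical_order <- function(data) {
  data[order(data$i, data$a, data$b, data$replicate_id), , drop = FALSE]
}

ls_engine <- function(data, model, law, options, extra_starts = NULL) {
  data <- canonical_order(as.data.frame(data))
  free_names <- free_param_names(model)
  w <- fit_weights(data, options$weighting)
  sw <- sqrt(w)
  resid_fn <- function(lp) {
    free <- stats::setNames(exp(lp), free_names)
    sw * (data$v - eval_law(expand_free(free), data$a, data$b, data$i, law))
  }
  starts <- build_starts(data, free_names, options, extra_starts)
  best <- NULL
  n_used <- 0L
  for (lp0 in starts) {
    n_used <- n_used + 1L
    res <- tryCatch(
      minpack.lm::nls.lm(par = lp0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = options$maxiter,
                           ftol = 1e-13, ptol = 1e-13, gtol = 1e-13)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15 * max(1, best$rss))
      best <- list(res = res, rss = rss, lp = res$par)
  }
  if (is.null(best))
    stop("all optimization starts failed", call. = FALSE)
  lp_hat <- stats::setNames(best$lp, free_names)
  converged <- best$res$info %in% 1:4
  est <- exp(lp_hat)

  # Gauss-Newton covariance from a central-difference Jacobian of the
  # weighted residuals with respect to the log-parameters.
  p <- length(lp_hat); n <- nrow(data)
  J <- matrix(0, n, p)
  hstep <- 1e-6
  for (k in seq_len(p)) {
    up <- lp_hat; up[k] <- up[k] + hstep
    dn <- lp_hat; dn[k] <- dn[k] - hstep
    J[, k] <- (resid_fn(up) - resid_fn(dn)) / (2 * hstep)
  }
  sigma2 <- if (n > p) best$rss / (n - p) else 0
  cov_log <- tryCatch(sigma2 * solve(crossprod(J)),
                      error = function(e) {
                        s <- svd(crossprod(J))
                        pos <- s$d > max(s$d) * 1e-12
                        sigma2 * s$v[, pos, drop = FALSE] %*%
                          (t(s$u[, pos, drop = FALSE]) / s$d[pos])
                      })
  d_nat <- diag(est, p)
  cov_nat <- d_nat %*% cov_log %*% d_nat
  dimnames(cov_nat) <- list(free_names, free_names)
  se_nat <- sqrt(pmax(diag(cov_nat), 0))

  list(free = est, se = stats::setNames(se_nat, free_names),
       covariance = cov_nat, rss = best$rss, n_obs = n,
       converged = converged, n_starts_used = n_used, data = data)
}

boundary_flags <- function(free, data) {
  rng_s <- range(c(data$a[data$a > 0], data$b[data$b > 0]))
  imax <- if (any(data$i > 0)) max(data$i) else NA_real_
  flag <- logical(length(free)); names(flag) <- names(free)
  for (nm in names(free)) {
    sc <- switch(nm,
      vmax = NULL,
      ka = , kb = , kia = rng_s,
      kis = , kii = , ki = if (is.na(imax)) NULL else c(imax, imax))
    if (is.null(sc)) next
    flag[nm] <- free[nm] < sc[1] * 1e-4 || free[nm] > sc[2] * 1e4
  }
  flag
}

make_fit_result <- function(eng, model, law, options, data) {
  free <- eng$free
  th <- expand_free(free)
  est <- structure(list(vmax = th[["vmax"]], ka = th[["ka"]],
                        kb = th[["kb"]], kia = th[["kia"]],
                        kis = th[["kis"]], kii = th[["kii"]],
                        vmax_unit = "as input"),
                   class = "kinetic_parameters")
  se <- eng$se
  if (model == "noncompetitive") {
    se <- c(se[c("vmax", "ka", "kb", "kia")],
            kis = unname(se[["ki"]]), kii = unname(se[["ki"]]))
  }
  structure(list(model = model, law = law, estimates = est,
                 standard_errors = se, covariance = eng$covariance,
                 rss = eng$rss, n_obs = eng$n_obs,
                 converged = eng$converged,
                 n_starts_used = eng$n_starts_used,
                 seed = options$seed, weighting = options$weighting,
                 boundary = boundary_flags(free, eng$data)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, digits = 4, ...) {
  cat(sprintf("Kinetic fit: model '%s' (law '%s'), %d observations\n",
              x$model, x$law, x$n_obs))
  cat(sprintf("  rss = %s | converged: %s | starts used: %d\n",
              format(x$rss, digits = digits), x$converged, x$n_starts_used))
  e <- x$estimates
  nm <- c("vmax", "ka", "kb", "kia", "kis", "kii")
  for (n2 in nm) {
    if (is.na(e[[n2]])) next
    se <- x$standard_errors[n2]
    bflag <- if (n2 %in% names(x$boundary)) x$boundary[[n2]]
             else if (n2 %in% c("kis", "kii") && "ki" %in% names(x$boundary))
               x$boundary[["ki"]] else FALSE
    cat(sprintf("  %-4s = %s +/- %s%s\n", n2,
                format(e[[n2]], digits = digits),
                if (is.na(se)) "NA" else format(se, digits = digits),
                if (isTRUE(bflag)) "  [boundary]" else ""))
  }
  if (any(x$boundary)) cat("  note: boundary-flagged parameters are weakly",
                           "identified by this design\n")
  invisible(x)
}

check_dataset_size <- function(data, n_free) {
  pts <- unique(data[c("a", "b", "i")])
  if (nrow(pts) < n_free + 1)
    stop(sprintf(
      "under-determined design: %d distinct (a, b, i) points for %d free parameters",
      nrow(pts), n_free), call. = FALSE)
}

#' Global fit of the ordered bi-bi rate law
#'
#' Least-squares estimation of `vmax`, `ka`, `kb` and `kia` from an
#' uninhibited two-substrate velocity dataset by multi-start
#' Levenberg-Marquardt optimization in log-parameter space (see
#' [fit_options()]).  Standard errors come from the Gauss-Newton
#' approximation to the covariance at the optimum.
#'
#' @param data A [velocity_dataset()] or data frame with columns `a`, `b`,
#'   `i`, `v`; all leucine concentrations must be 0.
#' @param options A [fit_options()] object.
#' @return An object of class `fit_result`: `estimates`
#'   ([kinetic_parameters()]), `standard_errors`, `covariance` (natural
#'   scale, free parameters), `rss`, `n_obs`, `converged`, `n_starts_used`,
#'   `seed`, and per-parameter `boundary` flags marking estimates that
#'   escaped the concentration scale of the design.
#' @examples
#' d <- simulate_velocity_grid(klleu4_parameters(),
#'                             default_grid_design("KlLeu4"),
#'                             noise_model(0, seed = 1))
#' fit_bibi(d)
#' @export
fit_bibi <- function(data, options = fit_options()) {
  data <- as_velocity_df(data)
  if (any(data$i != 0))
    stop("fit_bibi expects an inhibitor-free dataset (all i == 0); ",
         "use fit_inhibition for leucine series", call. = FALSE)
  if (length(unique(data$a)) < 2 || length(unique(data$b)) < 2)
    stop("design error: both substrates must be varied", call. = FALSE)
  check_dataset_size(data, 4L)
  eng <- ls_engine(data, "bibi", "bibi", options)
  make_fit_result(eng, "bibi", "bibi", options, data)
}

#' Global fit of an inhibited rate law across leucine levels
#'
#' Fits all leucine levels simultaneously with shared `vmax`, `ka`, `kb`,
#' `kia` and the inhibition constant(s) of the requested mechanism -- a
#' single global fit, not per-curve fits.
#'
#' @inheritParams fit_bibi
#' @param kind Inhibition mechanism: `"competitive"` (`kis` only),
#'   `"uncompetitive"` (`kii` only), `"noncompetitive"` (`kis = kii`,
#'   one shared constant) or `"mixed"` (both free).
#' @param which_apparent Algebraic form to fit: `"full"` (the internally
#'   consistent two-substrate law, default), `"varied_a"` (acetyl-CoA-varied
#'   replot form; identical to `"full"`), or `"varied_b"` (alpha-KIV-varied
#'   replot form, which groups the `kb*A` term with the slope factor).
#' @param extra_starts Optional list of named full start vectors (natural
#'   scale) appended to the generated multi-start set.
#' @return A `fit_result`; for `"noncompetitive"` the shared constant is
#'   reported as both `kis` and `kii`.
#' @export
fit_inhibition <- function(data,
                           kind = c("mixed", "competitive", "uncompetitive",
                                    "noncompetitive"),
                           which_apparent = c("full", "varied_a", "varied_b"),
                           options = fit_options(), extra_starts = NULL) {
  kind <- match.arg(kind)
  which_apparent <- match.arg(which_apparent)
  data <- as_velocity_df(data)
  ilv <- unique(data$i)
  if (length(ilv) < 2 || !any(ilv == 0))
    stop("inhibition fits need >= 2 distinct leucine levels including 0",
         call. = FALSE)
  check_dataset_size(data, length(free_param_names(kind)))
  eng <- ls_engine(data, kind, which_apparent, options, extra_starts)
  make_fit_result(eng, kind, which_apparent, options, data)
}

as_velocity_df <- function(data) {
  df <- as.data.frame(data)
  need <- c("a", "b", "i", "v")
  if (!all(need %in% names(df)))
    stop("data must have columns a, b, i, v", call. = FALSE)
  if (is.null(df$replicate_id)) df$replicate_id <- 1L
  if (any(!is.finite(df$v)))
    stop("non-finite velocities in data", call. = FALSE)
  check_conc(df$a, "a"); check_conc(df$b, "b"); check_conc(df$i, "i")
  df
}
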