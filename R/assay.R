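#' Absorbance trace container
#'
#' A 412 nm absorbance time series from the DTNB-coupled assay: free CoA
#' released by the synthase reacts with Ellman's reagent to give the NTB2-
#' chromophore, so the slope of the linear phase is proportional to the
#' reaction rate.
#'
#' @param time Time, seconds, strictly increasing, >= 10 points.
#' @param a412 Absorbance at 412 nm.
#' @param label Free-text identifier.
#' @return Object of classes `absorbance_trace` and `data.frame` with
#'   columns `time` and `a412`.
#' @export
absorbance_trace <- function(time, a412, label = "") {
  if (length(time) < 10) stop("trace needs >= 10 points", call. = FALSE)
  if (length(time) != length(a412))
    stop("time and a412 lengths differ", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  structure(data.frame(time = time, a412 = a412),
            label = label, class = c("absorbance_trace", "data.frame"))
}

#' Assay conditions for the DTNB-coupled rate measurement
#'
#' @param epsilon Extinction coefficient of NTB2- at 412 nm in
#'   mM^-1 cm^-1 (default 14.15, i.e. 14150 M^-1 cm^-1; see the package
#'   vignette for the unit convention).
#' @param path_cm Optical path length, cm.
#' @param volume_ml Reaction volume, mL.
#' @param protein_mg Protein mass in the cuvette, mg.
#' @param preincubation_s Seconds at the start of the trace excluded from
#'   rate estimation (thermal equilibration plus the burst of DTNB reacting
#'   with contaminant CoA in the acetyl-CoA stock).  `NULL` (default)
#'   triggers automatic burst detection in [estimate_initial_rate()].
#' @return An object of class `assay_conditions`.
#' @export
assay_conditions <- function(epsilon = 14.15, path_cm = 1, volume_ml = 1.0,
                             protein_mg = 1, preincubation_s = NULL) {
  for (nm in c("epsilon", "path_cm", "volume_ml"))
    if (get(nm) <= 0) stop(nm, " must be positive", call. = FALSE)
  if (protein_mg < 0) stop("protein_mg must be nonnegative", call. = FALSE)
  if (!is.null(preincubation_s) && preincubation_s < 0)
    stop("preincubation_s must be >= 0", call. = FALSE)
  structure(list(epsilon = epsilon, path_cm = path_cm,
                 volume_ml = volume_ml, protein_mg = protein_mg,
                 preincubation_s = preincubation_s),
            class = "assay_conditions")
}

# OLS slope/intercept/R2 of a412 ~ time (per-minute slope).  R2 of an exact
# fit (zero residual variance) is reported as 1 even when the signal is flat.
# `curvature` is the slope change across the window implied by a quadratic
# fit, in A/min -- the linearity diagnostic used by the window policy.
window_ols <- function(t_s, y) {
  n <- length(t_s)
  tm <- t_s / 60
  mx <- mean(tm); my <- mean(y)
  xc <- tm - mx
  sxx <- sum(xc^2)
  slope <- sum(xc * (y - my)) / sxx
  res <- y - my - slope * xc
  sstot <- sum((y - my)^2); ssres <- sum(res^2)
  r2 <- if (sstot <= .Machine$double.eps * n) 1 else 1 - ssres / sstot
  se <- if (n > 2) sqrt(ssres / (n - 2) / sxx) else NA_real_
  curv <- NA_real_
  if (n >= 5) {
    q <- stats::lm.fit(cbind(1, xc, xc^2), y)
    curv <- 2 * q$coefficients[3] * (max(tm) - min(tm))
  }
  list(slope = slope, r_squared = max(0, min(1, r2)), se = se, n = n,
       curvature = curv)
}

# Automatic burst settling time: first time point where the rolling-window
# slope drops below `factor` times the final-third slope.
detect_preincubation <- function(trace, roll_s = 30, factor = 5) {
  t <- trace$time; y <- trace$a412
  third <- t >= t[1] + 2 * diff(range(t)) / 3
  ref <- abs(window_ols(t[third], y[third])$slope)
  for (k in seq_along(t)) {
    idx <- which(t >= t[k] & t <= t[k] + roll_s)
    if (length(idx) < 4) break
    if (abs(window_ols(t[idx], y[idx])$slope) <= factor * max(ref, 1e-12))
      return(t[k])
  }
  t[1]
}

#' Initial rate from an absorbance trace
#'
#' Scans 60 s windows (by default) after the preincubation period and
#' returns the ordinary least-squares slope of the earliest window that is
#' acceptably linear: R2 at least `r2_min` and quadratic curvature implying
#' a slope change across the window of at most `curvature_max` times the
#' fitted slope (the curvature gate is what rejects windows still riding
#' the tail of the contaminant-CoA burst).  If no window qualifies, the
#' maximum-R2 window is used -- or, when even the best window shows no
#' coherent trend (R2 < 0.5, e.g. an enzyme-free blank), the slope over the
#' whole post-preincubation range -- and the estimate is flagged
#' `low_quality`.
#'
#' If the conditions do not fix `preincubation_s`, the burst settling time
#' is detected as the first time the rolling 30 s slope falls below 5x the
#' final-third slope.  Passing the known extract-addition time explicitly
#' is always at least as accurate.
#'
#' @param trace An [absorbance_trace()].
#' @param conditions An [assay_conditions()] (only `preincubation_s` used).
#' @param window_s Window width, seconds.
#' @param r2_min R2 acceptance threshold for a window.
#' @param curvature_max Maximum slope change across the window, as a
#'   fraction of the fitted slope.
#' @return Object of class `rate_estimate`: `dA412_per_min`, `window`
#'   (start, end in s), `r_squared`, `n_points`, `slope_se`, `low_quality`.
#' @export
estimate_initial_rate <- function(trace, conditions = assay_conditions(),
                                  window_s = 60, r2_min = 0.98,
                                  curvature_max = 0.02) {
  stopifnot(inherits(trace, "absorbance_trace"))
  pre <- conditions$preincubation_s
  if (is.null(pre)) pre <- detect_preincubation(trace)
  t <- trace$time; y <- trace$a412
  if (max(t) <= pre + window_s / 2)
    stop("trace does not extend beyond the preincubation period",
         call. = FALSE)
  cand_starts <- t[t >= pre & t + window_s <= max(t) + 1e-9]
  if (!length(cand_starts)) cand_starts <- pre
  best <- NULL; chosen <- NULL
  for (ts in cand_starts) {
    idx <- which(t >= ts & t <= ts + window_s)
    if (length(idx) < 4) next
    w <- window_ols(t[idx], y[idx])
    w$window <- c(ts, ts + window_s)
    if (is.null(best) || w$r_squared > best$r_squared) best <- w
    lin <- !is.na(w$curvature) &&
      abs(w$curvature) <= max(curvature_max * abs(w$slope), 1e-9)
    if (w$r_squared >= r2_min && lin) { chosen <- w; break }
  }
  if (is.null(best))
    stop("trace too short: no candidate window has >= 4 points",
         call. = FALSE)
  low_quality <- is.null(chosen)
  if (low_quality) {
    chosen <- best
    if (best$r_squared < 0.5) {
      idx <- which(t >= pre)
      chosen <- window_ols(t[idx], y[idx])
      chosen$window <- c(pre, max(t))
    }
  }
  structure(list(dA412_per_min = chosen$slope, window = chosen$window,
                 r_squared = chosen$r_squared, n_points = chosen$n,
                 slope_se = chosen$se, low_quality = low_quality),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Initial rate: %s A/min (window %g-%g s, n = %d, R2 = %s)%s\n",
    format(x$dA412_per_min, digits = digits), x$window[1], x$window[2],
    x$n_points, format(x$r_squared, digits = digits),
    if (x$low_quality) " [low quality: no window met the R2 threshold]" else ""))
  invisible(x)
}

#' Convert an absorbance rate to a specific activity
#'
#' Beer-Lambert conversion of the 412 nm slope to NTB2- (= CoA) production,
#' normalized to protein:
#' `nmol min^-1 mg^-1 = dA/min / (epsilon * path_cm) [mM/min] * volume_ml
#'  [-> umol/min, x1000 -> nmol/min] / protein_mg`.
#' The unit audit is attached as the `"conversion"` attribute.
#'
#' @param rate A [estimate_initial_rate()] result, or a numeric dA412/min.
#' @param conditions An [assay_conditions()] with `protein_mg` set.
#' @return Object of class `specific_activity`: value in
#'   nmol CoA min^-1 mg^-1.
#' @examples
#' to_specific_activity(0.1415, assay_conditions(protein_mg = 0.5))
#' @export
to_specific_activity <- function(rate, conditions) {
  stopifnot(inherits(conditions, "assay_conditions"))
  da <- if (inherits(rate, "rate_estimate")) rate$dA412_per_min
        else as.numeric(rate)
  if (conditions$protein_mg == 0)
    stop("protein_mg is 0: set the protein mass in assay_conditions() ",
         "before normalizing", call. = FALSE)
  mM_per_min <- da / (conditions$epsilon * conditions$path_cm)
  nmol_per_min <- mM_per_min * conditions$volume_ml * 1000
  value <- nmol_per_min / conditions$protein_mg
  structure(list(value = value),
            conversion = c(dA412_per_min = da, mM_per_min = mM_per_min,
                           nmol_per_min = nmol_per_min,
                           protein_mg = conditions$protein_mg),
            class = "specific_activity")
}

#' @export
print.specific_activity <- function(x, digits = 4, ...) {
  cat(sprintf("Specific activity: %s nmol CoA min^-1 mg^-1\n",
              format(x$value, digits = digits)))
  invisible(x)
}

#' Normalize specific activities to the uninhibited reference
#'
#' Divides each activity by the activity at the reference leucine level
#' (default 0 mM), producing the dose-response table [estimate_ic50()]
#' consumes.
#'
#' @param activities Data frame with columns `i` (leucine, mM) and
#'   `specific_activity` (or a list of [to_specific_activity()] results
#'   named by their leucine level).
#' @param reference_level Leucine level defining 100% activity.
#' @return Data frame with columns `i` and `relative_activity`; the
#'   reference row maps to exactly 1.
#' @export
relative_activity_series <- function(activities, reference_level = 0) {
  if (is.list(activities) && !is.data.frame(activities) &&
      all(vapply(activities, inherits, logical(1), "specific_activity"))) {
    activities <- data.frame(
      i = as.numeric(names(activities)),
      specific_activity = vapply(activities, `[[`, numeric(1), "value"))
  }
  df <- as.data.frame(activities)
  if (!all(c("i", "specific_activity") %in% names(df)))
    stop("activities needs columns i and specific_activity", call. = FALSE)
  ref <- df$specific_activity[df$i == reference_level]
  if (!length(ref))
    stop("reference level ", reference_level, " not present", call. = FALSE)
  ref <- mean(ref)
  if (ref <= 0)
    stop("reference activity is not positive; cannot normalize",
         call. = FALSE)
  out <- data.frame(i = df$i, relative_activity = df$specific_activity / ref)
  out$relative_activity[out$i == reference_level] <- 1
  out[order(out$i), , drop = FALSE]
}
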