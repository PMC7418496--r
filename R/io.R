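#' Read and write the package's CSV dialects
#'
#' Velocity tables use the header `acetylcoa_mM, kiv_mM, leucine_mM,
#' velocity` (optional `replicate_id`); dose-response tables use
#' `leucine_mM, relative_activity`; absorbance traces use `time_s, a412`.
#' All files are comma-separated, dot-decimal, UTF-8.
#'
#' @param path File path.
#' @param enzyme_label,design_note Metadata stored on the returned dataset.
#' @return `read_velocity_csv()` a [velocity_dataset()];
#'   `read_dose_response_csv()` a data frame with columns `i`,
#'   `relative_activity`; `read_trace_csv()` an [absorbance_trace()].
#' @export
read_velocity_csv <- function(path, enzyme_label = basename(path),
                              design_note = "") {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("acetylcoa_mM", "kiv_mM", "leucine_mM", "velocity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("velocity CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  obs <- data.frame(a = df$acetylcoa_mM, b = df$kiv_mM, i = df$leucine_mM,
                    v = df$velocity)
  if (!is.null(df$replicate_id)) obs$replicate_id <- df$replicate_id
  velocity_dataset(obs, enzyme_label = enzyme_label,
                   design_note = design_note)
}

#' @rdname read_velocity_csv
#' @param data A [velocity_dataset()] or compatible data frame.
#' @export
write_velocity_csv <- function(data, path) {
  df <- as_velocity_df(data)
  out <- data.frame(acetylcoa_mM = df$a, kiv_mM = df$b, leucine_mM = df$i,
                    velocity = df$v, replicate_id = df$replicate_id)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_velocity_csv
#' @export
read_dose_response_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  miss <- setdiff(c("leucine_mM", "relative_activity"), names(df))
  if (length(miss))
    stop("dose-response CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  data.frame(i = df$leucine_mM, relative_activity = df$relative_activity)
}

#' @rdname read_velocity_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  miss <- setdiff(c("time_s", "a412"), names(df))
  if (length(miss))
    stop("trace CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  absorbance_trace(time = df$time_s, a412 = df$a412,
                   label = basename(path))
}

#' Serialize a fit result
#'
#' `fit_report_json()` writes estimates, standard errors, covariance, rss
#' and the convergence record as JSON; `fit_report_csv()` writes a flat
#' one-row-per-parameter table.
#'
#' @param fit A `fit_result` from [fit_bibi()] or [fit_inhibition()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
fit_report_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  e <- fit$estimates
  obj <- list(
    model = fit$model, law = fit$law,
    estimates = list(vmax = e$vmax, ka = e$ka, kb = e$kb, kia = e$kia,
                     kis = e$kis, kii = e$kii),
    standard_errors = as.list(fit$standard_errors),
    covariance = unclass(fit$covariance),
    rss = fit$rss, n_obs = fit$n_obs, converged = fit$converged,
    n_starts_used = fit$n_starts_used, seed = fit$seed,
    weighting = fit$weighting, boundary = as.list(fit$boundary))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname fit_report_json
#' @export
fit_report_csv <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  e <- fit$estimates
  nm <- c("vmax", "ka", "kb", "kia", "kis", "kii")
  est <- vapply(nm, function(n) if (is.na(e[[n]])) NA_real_ else e[[n]],
                numeric(1))
  se <- fit$standard_errors[nm]
  out <- data.frame(parameter = nm, estimate = est, standard_error = se,
                    model = fit$model, rss = fit$rss,
                    converged = fit$converged)
  out <- out[!is.na(out$estimate), ]
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read assay conditions from a YAML or JSON config file
#'
#' The file holds a flat mapping of [assay_conditions()] fields (`epsilon`,
#' `path_cm`, `volume_ml`, `protein_mg`, `preincubation_s`); unknown keys
#' are rejected by name so typos cannot silently fall back to defaults.
#' `.yaml`/`.yml` files need the yaml package; anything else is parsed as
#' JSON.
#'
#' @param path Config file path.
#' @return An [assay_conditions()] object.
#' @export
read_assay_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("epsilon", "path_cm", "volume_ml", "protein_mg",
             "preincubation_s")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown assay config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(assay_conditions, cfg)
}

#' Write a double-reciprocal table as CSV
#'
#' @param lw A [lineweaver_points()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
lineweaver_csv <- function(lw, path) {
  stopifnot(inherits(lw, "lineweaver"))
  utils::write.csv(lw$points, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
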