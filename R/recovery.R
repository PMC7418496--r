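#' Configuration for a parameter-recovery experiment
#'
#' A recovery experiment repeatedly simulates a dataset from known
#' generating parameters, refits it, and summarizes how well the estimates
#' recover the truth.  All randomness flows from `master_seed`: replicate
#' `r` uses seed `(master_seed - 1) * n_replicates + r` (disjoint streams
#' for different master seeds), so any subset of replicates is
#' reproducible on its own.
#'
#' @param generating_parameters A [kinetic_parameters()] object (the truth).
#' @param design A [grid_design()] / [default_inhibition_design()] object.
#' @param model_to_fit `"bibi"` or an inhibition kind (see
#'   [fit_inhibition()]).
#' @param proportional_sd Proportional noise SD passed to [noise_model()].
#' @param n_replicates Number of simulated datasets.
#' @param master_seed Master seed.
#' @param enzyme_label Label echoed into reports.
#' @param fit_opts A [fit_options()] object used for every refit.
#' @param output_dir Optional directory; when set, the report and a run
#'   manifest are written there as JSON.
#' @return An object of class `recovery_config`.
#' @export
recovery_config <- function(generating_parameters, design,
                            model_to_fit = "bibi",
                            proportional_sd = 0.03, n_replicates = 100L,
                            master_seed = 1L, enzyme_label = "",
                            fit_opts = fit_options(),
                            output_dir = NULL) {
  stopifnot(inherits(generating_parameters, "kinetic_parameters"),
            inherits(design, c("grid_design", "slice_design")))
  model_to_fit <- match.arg(model_to_fit, c("bibi", "competitive",
                                            "uncompetitive",
                                            "noncompetitive", "mixed"))
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (model_to_fit != "bibi")
    check_inhibition_kind(generating_parameters, model_to_fit)
  structure(list(generating_parameters = generating_parameters,
                 design = design, model_to_fit = model_to_fit,
                 proportional_sd = proportional_sd,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 enzyme_label = enzyme_label, fit_opts = fit_opts,
                 output_dir = output_dir),
            class = "recovery_config")
}

recovered_names <- function(model) {
  switch(model,
    bibi = c("vmax", "ka", "kb", "kia"),
    competitive = c("vmax", "ka", "kb", "kia", "kis"),
    uncompetitive = c("vmax", "ka", "kb", "kia", "kii"),
    c("vmax", "ka", "kb", "kia", "kis", "kii"))
}

#' Run a kinetic parameter-recovery experiment
#'
#' For each replicate: simulate a velocity dataset from the generating
#' parameters and design ([simulate_velocity_grid()]), refit with the
#' requested model ([fit_bibi()] or [fit_inhibition()]), and record the
#' estimates.  Non-converged replicates are excluded from the summaries and
#' counted.  The per-parameter summary reports the generating value, median
#' and mean estimate, relative bias of the median, replicate SD and CV, and
#' the coverage of the approximate 95% Wald interval.
#'
#' @param config A [recovery_config()].
#' @param verbose If `TRUE`, log one line per replicate.
#' @return An object of class `recovery_report`: `summary` (one row per
#'   parameter), `estimates` (replicate x parameter matrix), `n_converged`,
#'   `n_replicates`, `seeds_used`, `degraded` (TRUE when more than 20% of
#'   replicates failed to converge), `caveats`.
#' @examples
#' cfg <- recovery_config(klleu4_parameters(), default_grid_design("KlLeu4"),
#'                        "bibi", proportional_sd = 0, n_replicates = 1,
#'                        fit_opts = fit_options(n_starts = 2))
#' run_parameter_recovery(cfg)$summary
#' @export
run_parameter_recovery <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "recovery_config"))
  pars <- recovered_names(config$model_to_fit)
  gen <- config$generating_parameters
  seeds <- (config$master_seed - 1L) * config$n_replicates +
    seq_len(config$n_replicates)
  est <- matrix(NA_real_, config$n_replicates, length(pars),
                dimnames = list(NULL, pars))
  ses <- est
  converged <- logical(config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    nm <- noise_model(proportional_sd = config$proportional_sd,
                      seed = seeds[r])
    d <- simulate_velocity_grid(gen, config$design, nm,
                                enzyme_label = config$enzyme_label)
    fit <- tryCatch({
      if (config$model_to_fit == "bibi") fit_bibi(d, config$fit_opts)
      else fit_inhibition(d, config$model_to_fit, "full", config$fit_opts)
    }, error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      converged[r] <- TRUE
      for (p in pars) {
        est[r, p] <- fit$estimates[[p]]
        ses[r, p] <- fit$standard_errors[[p]]
      }
    }
    if (verbose)
      message(sprintf("replicate %d seed %d converged %s rss %s", r,
                      seeds[r], !is.null(fit) && fit$converged,
                      if (is.null(fit)) "NA" else format(fit$rss)))
  }
  ok <- which(converged)
  summ <- do.call(rbind, lapply(pars, function(p) {
    g <- gen[[p]]
    e <- est[ok, p]; s <- ses[ok, p]
    cover <- mean(g >= e - 1.96 * s & g <= e + 1.96 * s, na.rm = TRUE)
    data.frame(parameter = p, generating_value = g,
               median_estimate = stats::median(e), mean_estimate = mean(e),
               relative_bias = (stats::median(e) - g) / g,
               sd = stats::sd(e),
               cv = stats::sd(e) / mean(e),
               ci95_coverage = cover)
  }))
  caveats <- paste(
      "kia enters the rate law only through the small kia*kb denominator",
      "term and is weakly identified: expect replicate-to-replicate spread",
      "well above that of ka.")
  report <- structure(list(summary = summ, estimates = est[ok, , drop = FALSE],
                           n_converged = length(ok),
                           n_replicates = config$n_replicates,
                           seeds_used = seeds,
                           degraded = length(ok) < 0.8 * config$n_replicates,
                           caveats = caveats,
                           kind = "kinetic_parameters",
                           enzyme_label = config$enzyme_label),
                      class = "recovery_report")
  maybe_write_report(report, config)
  report
}

#' Run an IC50 recovery experiment
#'
#' Dose-response analogue of [run_parameter_recovery()]: each replicate
#' simulates a relative-activity curve from a known IC50
#' ([simulate_dose_response()]) and refits it with [estimate_ic50()].
#' Replicates whose curves fail the identifiability precondition (activities
#' not bracketing 0.5) are excluded and counted, never fatal.
#'
#' @param ic50_true Generating IC50, mM.
#' @param i_levels Leucine levels, mM.
#' @param proportional_sd Proportional noise SD.
#' @param n_replicates Number of simulated curves.
#' @param master_seed Master seed (replicate `r` uses seed
#'   `(master_seed - 1) * n_replicates + r`).
#' @param hill Fit the Hill slope too (default: fixed at 1).
#' @param enzyme_label Label echoed into the report.
#' @param output_dir Optional report directory.
#' @return A `recovery_report` whose single summarized parameter is `ic50`.
#' @export
run_ic50_recovery <- function(ic50_true,
                              i_levels = c(0, 0.005, 0.01, 0.02, 0.04,
                                           0.08, 0.16),
                              proportional_sd = 0.05, n_replicates = 100L,
                              master_seed = 1L, hill = FALSE,
                              enzyme_label = "", output_dir = NULL) {
  stopifnot(ic50_true > 0, n_replicates >= 1)
  seeds <- (as.integer(master_seed) - 1L) * as.integer(n_replicates) +
    seq_len(n_replicates)
  est <- rep(NA_real_, n_replicates)
  ses <- est
  ok <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    dr <- simulate_dose_response(ic50_true, i_levels,
                                 noise_model(proportional_sd,
                                             seed = seeds[r]))
    fit <- tryCatch(estimate_ic50(dr, hill = hill), error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      ok[r] <- TRUE
      est[r] <- fit$ic50
      ses[r] <- fit$standard_error
    }
  }
  e <- est[ok]; s <- ses[ok]
  summ <- data.frame(
    parameter = "ic50", generating_value = ic50_true,
    median_estimate = stats::median(e), mean_estimate = mean(e),
    relative_bias = (stats::median(e) - ic50_true) / ic50_true,
    sd = stats::sd(e), cv = stats::sd(e) / mean(e),
    ci95_coverage = mean(ic50_true >= e - 1.96 * s &
                         ic50_true <= e + 1.96 * s, na.rm = TRUE))
  report <- structure(list(summary = summ,
                           estimates = matrix(e, ncol = 1,
                                              dimnames = list(NULL, "ic50")),
                           n_converged = sum(ok),
                           n_replicates = n_replicates, seeds_used = seeds,
                           degraded = sum(ok) < 0.8 * n_replicates,
                           caveats = character(),
                           kind = "ic50", enzyme_label = enzyme_label),
                      class = "recovery_report")
  if (!is.null(output_dir))
    maybe_write_report(report, list(output_dir = output_dir,
                                    master_seed = master_seed,
                                    enzyme_label = enzyme_label))
  report
}

#' @export
print.recovery_report <- function(x, digits = 4, ...) {
  cat(sprintf("Recovery report (%s%s): %d/%d replicates converged%s\n",
              x$kind,
              if (nzchar(x$enzyme_label)) paste0(", ", x$enzyme_label) else "",
              x$n_converged, x$n_replicates,
              if (x$degraded) " [DEGRADED: > 20% non-convergence]" else ""))
  print(format(x$summary, digits = digits), row.names = FALSE)
  for (cv in x$caveats) cat("caveat:", cv, "\n")
  invisible(x)
}

report_to_json_obj <- function(report) {
  list(summary = report$summary, n_converged = report$n_converged,
       n_replicates = report$n_replicates,
       seeds_used = report$seeds_used, degraded = report$degraded,
       caveats = report$caveats, kind = report$kind,
       enzyme_label = report$enzyme_label,
       estimates = unclass(report$estimates))
}

maybe_write_report <- function(report, config) {
  dir <- config$output_dir
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report_to_json_obj(report),
                       file.path(dir, "recovery_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("ipmskinetics")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      usetz = TRUE),
                   master_seed = config$master_seed,
                   enzyme_label = config$enzyme_label)
  if (inherits(config, "recovery_config")) {
    g <- config$generating_parameters
    manifest$generating_parameters <- list(vmax = g$vmax, ka = g$ka,
                                           kb = g$kb, kia = g$kia,
                                           kis = g$kis, kii = g$kii)
    manifest$model_to_fit <- config$model_to_fit
    manifest$proportional_sd <- config$proportional_sd
    manifest$n_replicates <- config$n_replicates
  }
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(NULL)
}

#' Regenerate the reference kinetic table as a recovery experiment
#'
#' Runs the two canonical noiseless round-trips -- for each isozyme,
#' simulate its uninhibited saturation grid and leucine-inhibition slices
#' from the reference parameters ([klleu4_parameters()],
#' [klleu4bis_parameters()]), refit with the ordered bi-bi law and the
#' global mixed-inhibition law -- and tabulates recovered versus reference
#' values side by side with a pass/fail call at `tolerance` (default 0.1%
#' relative, the noiseless-round-trip contract).
#'
#' @param output_dir Optional directory for JSON/CSV copies of the table.
#' @param tolerance Relative tolerance for the pass column.
#' @param fit_opts A [fit_options()] object.
#' @return Object of class `reference_table_comparison`: a data frame with columns
#'   `enzyme`, `parameter`, `reference`, `recovered`, `relative_diff`,
#'   `pass`.
#' @export
reproduce_reference_table <- function(output_dir = NULL, tolerance = 1e-3,
                             fit_opts = fit_options(n_starts = 4)) {
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir))
      dir.create(output_dir, recursive = TRUE)
    probe <- file.path(output_dir, ".write_probe")
    ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE,
                   error = function(e) FALSE)
    if (!isTRUE(ok))
      stop("output_dir is not writable: ", output_dir, call. = FALSE)
    unlink(probe)
  }
  enzymes <- list(KlLeu4 = klleu4_parameters(),
                  KlLeu4BIS = klleu4bis_parameters())
  rows <- list()
  for (nm in names(enzymes)) {
    gen <- enzymes[[nm]]
    grid <- simulate_velocity_grid(gen, default_grid_design(nm),
                                   noise_model(0, seed = 1L),
                                   enzyme_label = nm)
    fb <- fit_bibi(grid, fit_opts)
    slices <- simulate_velocity_grid(gen, default_inhibition_design(),
                                     noise_model(0, seed = 1L),
                                     enzyme_label = nm)
    fi <- fit_inhibition(slices, "mixed", "full", fit_opts)
    for (p in c("vmax", "ka", "kb", "kia")) {
      rows[[length(rows) + 1]] <- data.frame(
        enzyme = nm, parameter = p, reference = gen[[p]],
        recovered = fb$estimates[[p]])
    }
    for (p in c("kis", "kii")) {
      rows[[length(rows) + 1]] <- data.frame(
        enzyme = nm, parameter = p, reference = gen[[p]],
        recovered = fi$estimates[[p]])
    }
  }
  tab <- do.call(rbind, rows)
  tab$relative_diff <- abs(tab$recovered - tab$reference) / tab$reference
  tab$pass <- tab$relative_diff <= tolerance
  tab <- structure(tab, tolerance = tolerance,
                   class = c("reference_table_comparison", "data.frame"))
  if (!is.null(output_dir)) {
    utils::write.csv(as.data.frame(tab),
                     file.path(output_dir, "reference_table_comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.data.frame(tab),
                         file.path(output_dir, "reference_table_comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  tab
}

#' @export
print.reference_table_comparison <- function(x, digits = 6, ...) {
  cat(sprintf(
    "Reference-table recovery (noiseless round-trip, tolerance %g%%)\n",
    100 * attr(x, "tolerance")))
  df <- as.data.frame(x)
  df$reference <- format(df$reference, digits = digits)
  df$recovered <- format(df$recovered, digits = digits)
  df$relative_diff <- format(df$relative_diff, digits = 3)
  df$pass <- ifelse(df$pass, "pass", "FAIL")
  print(df, row.names = FALSE)
  invisible(x)
}
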