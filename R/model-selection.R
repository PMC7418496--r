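#' Rank inhibition mechanisms by small-sample-corrected AIC
#'
#' Fits the competitive, uncompetitive, noncompetitive and mixed mechanisms
#' globally to the same leucine-series dataset and ranks them by AICc
#' computed from the Gaussian least-squares likelihood,
#' `AICc = n log(rss/n) + 2k + 2k(k+1)/(n-k-1)` with `k` counting the free
#' rate-law parameters plus the error variance.  The mixed fit is seeded
#' additionally from each simpler converged solution (with any absent
#' constant set far above the largest inhibitor level), which guarantees the
#' nested residual-sum-of-squares ordering at convergence.
#'
#' Parsimony tie-break: if a model with fewer parameters lies within
#' `delta_cut` AICc units of the minimum, the simpler model is reported as
#' best (near-ties do not justify the extra constant).
#'
#' @inheritParams fit_inhibition
#' @param delta_cut AICc margin for the parsimony tie-break (default 2).
#' @return An object of class `model_comparison`: `table` (model, rss,
#'   n_params, aicc, delta_aicc, converged), `best` (the selected kind),
#'   `fits` (named list of `fit_result`s), `excluded` (models dropped for
#'   non-convergence).
#' @examples
#' d <- simulate_velocity_grid(klleu4_parameters(),
#'                             default_inhibition_design(),
#'                             noise_model(0.03, seed = 7))
#' compare_inhibition_models(d, options = fit_options(n_starts = 3))
#' @export
compare_inhibition_models <- function(data, options = fit_options(),
                                      which_apparent = "full",
                                      delta_cut = 2) {
  data <- as_velocity_df(data)
  ilv <- unique(data$i)
  if (length(ilv) < 2 || !any(ilv == 0))
    stop("inhibition fits need >= 2 distinct leucine levels including 0",
         call. = FALSE)
  simple <- c("competitive", "uncompetitive", "noncompetitive")
  fits <- list()
  for (kind in simple)
    fits[[kind]] <- tryCatch(
      fit_inhibition(data, kind, which_apparent, options),
      error = function(e) NULL)

  # seed the mixed fit from every converged simpler solution
  big_k <- (if (any(data$i > 0)) max(data$i) else 1) * 1e3
  extra <- list()
  for (kind in simple) {
    f <- fits[[kind]]
    if (is.null(f) || !f$converged) next
    e <- f$estimates
    extra[[kind]] <- c(vmax = e$vmax, ka = e$ka, kb = e$kb, kia = e$kia,
                       kis = if (is.na(e$kis)) big_k else e$kis,
                       kii = if (is.na(e$kii)) big_k else e$kii)
  }
  fits$mixed <- tryCatch(
    fit_inhibition(data, "mixed", which_apparent, options,
                   extra_starts = unname(extra)),
    error = function(e) NULL)

  n <- nrow(data)
  rows <- lapply(names(fits), function(kind) {
    f <- fits[[kind]]
    if (is.null(f)) return(NULL)
    k <- length(free_param_names(kind)) + 1  # + error variance
    aicc <- n * log(f$rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    data.frame(model = kind, rss = f$rss, n_params = k, aicc = aicc,
               converged = f$converged)
  })
  tab <- do.call(rbind, rows)
  excluded <- c(setdiff(c(simple, "mixed"), tab$model),
                tab$model[!tab$converged])
  tab <- tab[tab$converged, , drop = FALSE]
  if (!nrow(tab))
    stop("no inhibition model converged on this dataset", call. = FALSE)
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  near <- tab[tab$delta_aicc < delta_cut, ]
  near <- near[order(near$n_params, near$aicc), ]
  best <- near$model[1]
  structure(list(table = tab, best = best, fits = fits,
                 excluded = excluded, delta_cut = delta_cut),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 4, ...) {
  cat("Inhibition mechanism comparison (AICc, parsimony margin",
      x$delta_cut, ")\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  cat("best:", x$best, "\n")
  if (length(x$excluded))
    cat("excluded (non-converged):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
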