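#' Double-reciprocal (Lineweaver-Burk) transformation and replot lines
#'
#' Transforms a leucine-series velocity dataset to 1/[S] versus 1/v for the
#' chosen varied substrate and summarizes each leucine level by an ordinary
#' least-squares line.  In mixed inhibition both the slopes and the
#' intercepts increase with inhibitor; competitive inhibition moves only the
#' slopes, uncompetitive only the intercepts.
#'
#' @param data A [velocity_dataset()] or data frame (`a`, `b`, `i`, `v`).
#' @param varied Which substrate is on the x axis: `"a"` (acetyl-CoA) or
#'   `"b"` (alpha-KIV).
#' @return An object of class `lineweaver`: `points` (inv_s, inv_v, i),
#'   `lines` (per-level slope, intercept, r_squared, n), `n_excluded`
#'   (observations dropped for nonpositive velocity or substrate).
#' @export
lineweaver_points <- function(data, varied = c("a", "b")) {
  varied <- match.arg(varied)
  df <- as_velocity_df(data)
  s <- df[[varied]]
  keep <- df$v > 0 & s > 0
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    warning(sprintf("%d observation(s) with nonpositive velocity or substrate excluded",
                    n_excluded), call. = FALSE)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 2) stop("too few usable observations", call. = FALSE)
  pts <- data.frame(inv_s = 1 / df[[varied]], inv_v = 1 / df$v, i = df$i)
  lines <- do.call(rbind, lapply(sort(unique(pts$i)), function(lv) {
    p <- pts[pts$i == lv, ]
    if (nrow(p) < 2 || length(unique(p$inv_s)) < 2)
      return(data.frame(i = lv, slope = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_, n = nrow(p)))
    fit <- stats::lm(inv_v ~ inv_s, data = p)
    # noiseless model data give exact lines; summary()'s perfect-fit
    # warning is expected there, not a data problem
    r2 <- suppressWarnings(summary(fit)$r.squared)
    data.frame(i = lv, slope = stats::coef(fit)[["inv_s"]],
               intercept = stats::coef(fit)[["(Intercept)"]],
               r_squared = r2, n = nrow(p))
  }))
  structure(list(points = pts, lines = lines, varied = varied,
                 n_excluded = n_excluded),
            class = "lineweaver")
}

#' @export
print.lineweaver <- function(x, digits = 4, ...) {
  cat(sprintf("Double-reciprocal summary (varied substrate: %s)\n", x$varied))
  print(format(x$lines, digits = digits), row.names = FALSE)
  if (x$n_excluded) cat("excluded observations:", x$n_excluded, "\n")
  invisible(x)
}
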