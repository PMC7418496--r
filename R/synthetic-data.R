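# Seed discipline: every stochastic generator takes its seed from a
# noise_model (or an explicit argument) and restores the caller's RNG state,
# so identical inputs give byte-identical outputs regardless of context.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Factorial design for initial-velocity measurements
#'
#' @param a_levels Acetyl-CoA levels, mM, strictly positive.
#' @param b_levels Alpha-KIV levels, mM, strictly positive.
#' @param i_levels Leucine levels, mM; may (and for inhibition studies must)
#'   include 0.  Default 0 (no inhibitor).
#' @param replicates Independent replicate measurements per grid point.
#' @return An object of class `grid_design`: the full crossing of the three
#'   level sets times `replicates`.
#' @seealso [default_grid_design()], [default_inhibition_design()]
#' @export
grid_design <- function(a_levels, b_levels, i_levels = 0, replicates = 1L) {
  check_conc(a_levels, "a_levels", allow_zero = FALSE)
  check_conc(b_levels, "b_levels", allow_zero = FALSE)
  check_conc(i_levels, "i_levels")
  stopifnot(length(replicates) == 1L, replicates >= 1)
  structure(list(a_levels = a_levels, b_levels = b_levels,
                 i_levels = i_levels, replicates = as.integer(replicates)),
            class = "grid_design")
}

log_levels <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

#' Standard substrate designs for the two K. lactis isozymes
#'
#' `default_grid_design()` returns the uninhibited two-substrate saturation
#' grid: 8 x 8 log-spaced levels over 0.002-0.1 mM acetyl-CoA x
#' 0.002-0.08 mM alpha-KIV for KlLeu4, and 0.008-0.1 x 0.01-0.25 mM for
#' KlLeu4BIS.  `default_inhibition_design()` returns the two saturation
#' slices used for leucine-inhibition studies -- acetyl-CoA varied
#' 0.002-0.06 mM at 0.25 mM alpha-KIV, and alpha-KIV varied 0.005-0.1 mM at
#' 0.1 mM acetyl-CoA (8 log-spaced levels each) -- crossed with leucine at
#' 0, 0.01, 0.02, 0.06 and 0.12 mM.
#'
#' @param enzyme `"KlLeu4"` or `"KlLeu4BIS"`.
#' @param n_levels Levels per varied-substrate axis.
#' @param replicates Replicates per design point.
#' @return A `grid_design` (inhibition designs: a list of two, class
#'   `slice_design`, one slice per varied substrate).
#' @export
default_grid_design <- function(enzyme = c("KlLeu4", "KlLeu4BIS"),
                                n_levels = 8L, replicates = 1L) {
  enzyme <- match.arg(enzyme)
  rng <- switch(enzyme,
    KlLeu4    = list(a = c(0.002, 0.1), b = c(0.002, 0.08)),
    KlLeu4BIS = list(a = c(0.008, 0.1), b = c(0.01, 0.25)))
  grid_design(a_levels = log_levels(rng$a[1], rng$a[2], n_levels),
              b_levels = log_levels(rng$b[1], rng$b[2], n_levels),
              i_levels = 0, replicates = replicates)
}

#' @rdname default_grid_design
#' @export
default_inhibition_design <- function(n_levels = 8L, replicates = 1L) {
  i_lv <- c(0, 0.01, 0.02, 0.06, 0.12)
  structure(list(
    varied_a = grid_design(a_levels = log_levels(0.002, 0.06, n_levels),
                           b_levels = 0.25, i_levels = i_lv,
                           replicates = replicates),
    varied_b = grid_design(a_levels = 0.1,
                           b_levels = log_levels(0.005, 0.1, n_levels),
                           i_levels = i_lv, replicates = replicates)),
    class = "slice_design")
}

#' Observation noise model for simulated measurements
#'
#' Simulated velocities are `v_true * (1 + e_p) + e_a` with
#' `e_p ~ N(0, proportional_sd^2)` and `e_a ~ N(0, additive_sd^2)`.
#' Proportional (constant-CV) noise is the default because
#' spectrophotometric initial-rate error scales with signal.
#'
#' @param proportional_sd Coefficient of variation of the multiplicative
#'   term (default 0.03, i.e. 3%).
#' @param additive_sd Additive noise SD in velocity units (default 0).
#' @param seed Integer seed; all randomness of a simulation flows from it.
#' @param negative_policy What to do with draws below zero: `"redraw"`
#'   (default; resample that observation's noise), `"clip"` (set to 0) or
#'   `"allow"`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(proportional_sd = 0.03, additive_sd = 0, seed = 1L,
                        negative_policy = c("redraw", "clip", "allow")) {
  stopifnot(proportional_sd >= 0, additive_sd >= 0)
  structure(list(proportional_sd = proportional_sd,
                 additive_sd = additive_sd, seed = as.integer(seed),
                 negative_policy = match.arg(negative_policy)),
            class = "noise_model")
}

noise_draw <- function(v_true, noise) {
  n <- length(v_true)
  v <- v_true * (1 + stats::rnorm(n, 0, noise$proportional_sd)) +
    (if (noise$additive_sd > 0) stats::rnorm(n, 0, noise$additive_sd) else 0)
  if (noise$negative_policy == "redraw") {
    for (tries in seq_len(1000L)) {
      bad <- which(v < 0 & v_true > 0)
      if (!length(bad)) break
      v[bad] <- v_true[bad] *
        (1 + stats::rnorm(length(bad), 0, noise$proportional_sd)) +
        (if (noise$additive_sd > 0)
           stats::rnorm(length(bad), 0, noise$additive_sd) else 0)
    }
  } else if (noise$negative_policy == "clip") v <- pmax(v, 0)
  v
}

#' Velocity dataset container
#'
#' A data frame of initial-velocity observations with design metadata.
#' Columns: `a`, `b`, `i` (mM) and `v` (velocity), plus `replicate_id`.
#'
#' @param observations Data frame with columns `a`, `b`, `i`, `v` (and
#'   optionally `replicate_id`, default 1).
#' @param enzyme_label Free-text enzyme identifier.
#' @param design_note Free-text provenance note.
#' @return An object of classes `velocity_dataset` and `data.frame`.
#' @export
velocity_dataset <- function(observations, enzyme_label = "",
                             design_note = "") {
  obs <- as.data.frame(observations)
  need <- c("a", "b", "i", "v")
  if (!all(need %in% names(obs)))
    stop("observations must have columns a, b, i, v", call. = FALSE)
  if (is.null(obs$replicate_id)) obs$replicate_id <- 1L
  obs <- obs[c("a", "b", "i", "v", "replicate_id")]
  structure(obs, enzyme_label = enzyme_label, design_note = design_note,
            class = c("velocity_dataset", "data.frame"))
}

#' @export
print.velocity_dataset <- function(x, ...) {
  cat(sprintf("Velocity dataset '%s': %d observations, %d leucine level(s)\n",
              attr(x, "enzyme_label"), nrow(x), length(unique(x$i))))
  if (nzchar(attr(x, "design_note")))
    cat(" ", attr(x, "design_note"), "\n")
  print(as.data.frame(utils::head(x, 6)), ...)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

expand_design <- function(design) {
  if (inherits(design, "slice_design")) {
    return(do.call(rbind, lapply(design, expand_design)))
  }
  g <- expand.grid(a = design$a_levels, b = design$b_levels,
                   i = design$i_levels, replicate_id = seq_len(design$replicates),
                   KEEP.OUT.ATTRS = FALSE)
  g
}

#' Simulate an initial-velocity dataset from the inhibited bi-bi law
#'
#' Evaluates [rate_inhibited()] on every point of the design and applies the
#' noise model.  Fully reproducible from `noise$seed`; replicate draws are
#' independent.
#'
#' @param params Generating [kinetic_parameters()].  Inhibition constants
#'   are required iff the design contains leucine levels above 0.
#' @param design A [grid_design()] or [default_inhibition_design()] object.
#' @param noise A [noise_model()]; `proportional_sd = 0` gives the exact
#'   model surface.
#' @param enzyme_label Label stored on the dataset.
#' @return A [velocity_dataset()].
#' @examples
#' d <- simulate_velocity_grid(klleu4_parameters(),
#'                             default_grid_design("KlLeu4"),
#'                             noise_model(0.03, seed = 1))
#' head(d)
#' @export
simulate_velocity_grid <- function(params, design,
                                   noise = noise_model(),
                                   enzyme_label = "") {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(design, c("grid_design", "slice_design")),
            inherits(noise, "noise_model"))
  g <- expand_design(design)
  if (any(g$i > 0) && is.na(params$kis) && is.na(params$kii))
    stop(paste("design includes leucine > 0 but the generating parameters",
               "carry no inhibition constant"), call. = FALSE)
  v_true <- rate_inhibited(params, g$a, g$b, g$i)
  g$v <- with_seed(noise$seed, noise_draw(v_true, noise))
  velocity_dataset(g, enzyme_label = enzyme_label,
                   design_note = sprintf(
                     "simulated: prop_sd=%g, add_sd=%g, seed=%d, policy=%s",
                     noise$proportional_sd, noise$additive_sd, noise$seed,
                     noise$negative_policy))
}

#' Simulate a leucine dose-response table
#'
#' Relative activity follows the one-site hyperbola
#' `rel(I) = 1 / (1 + I / ic50_true)` (exactly 1 at I = 0 before noise),
#' with multiplicative Gaussian noise from the noise model.
#'
#' @param ic50_true Generating IC50, mM (> 0).
#' @param i_levels Leucine levels, mM; default matches the crude-extract
#'   titration 0, 0.005, 0.01, 0.02, 0.04, 0.08, 0.16 mM.
#' @param noise A [noise_model()] (additive part ignored).
#' @return Data frame with columns `i` (mM) and `relative_activity`.
#' @export
simulate_dose_response <- function(ic50_true,
                                   i_levels = c(0, 0.005, 0.01, 0.02,
                                                0.04, 0.08, 0.16),
                                   noise = noise_model(0)) {
  stopifnot(length(ic50_true) == 1L, is.finite(ic50_true), ic50_true > 0)
  if (!length(i_levels)) stop("i_levels must be non-empty", call. = FALSE)
  check_conc(i_levels, "i_levels")
  rel_true <- 1 / (1 + i_levels / ic50_true)
  rel <- with_seed(noise$seed, noise_draw(rel_true, noise))
  data.frame(i = i_levels, relative_activity = rel)
}

#' Simulate a DTNB absorbance trace
#'
#' Absorbance at 412 nm versus time: a baseline, an exponential burst from
#' DTNB reacting with contaminant free CoA in the acetyl-CoA preparation,
#' the enzymatic linear phase, and optional Gaussian read noise:
#'
#' `a412(t) = baseline + amplitude * (1 - exp(-t / tau_s)) +
#'            rate * max(0, t - linear_start_s) / 60 + noise`
#'
#' @param true_rate_a_per_min Enzymatic slope, absorbance units per minute.
#' @param duration_s Trace length, seconds (> burst settling time).
#' @param burst List with `amplitude` (absorbance) and `tau_s` (time
#'   constant, s) of the contaminant-CoA burst; `amplitude = 0` disables it.
#' @param noise_sd Gaussian read-noise SD, absorbance units.
#' @param seed Integer seed.
#' @param baseline Absorbance offset at t = 0.
#' @param linear_start_s Time at which the enzymatic reaction starts
#'   (extract addition), s.
#' @param dt_s Sampling interval, s.
#' @return An [absorbance_trace()].
#' @export
simulate_trace <- function(true_rate_a_per_min, duration_s,
                           burst = list(amplitude = 0, tau_s = 60),
                           noise_sd = 0, seed = 1L, baseline = 0.05,
                           linear_start_s = 0, dt_s = 1) {
  stopifnot(duration_s > 0, dt_s > 0, noise_sd >= 0,
            burst$amplitude >= 0, burst$tau_s > 0)
  t <- seq(0, duration_s, by = dt_s)
  a <- baseline + burst$amplitude * (1 - exp(-t / burst$tau_s)) +
    true_rate_a_per_min * pmax(0, t - linear_start_s) / 60
  if (noise_sd > 0)
    a <- a + with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  absorbance_trace(time = t, a412 = a,
                   label = sprintf("simulated rate=%g A/min seed=%d",
                                   true_rate_a_per_min, seed))
}
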