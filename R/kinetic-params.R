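#' Kinetic parameter set for an ordered bi-bi enzyme
#'
#' Bundles the constants of the steady-state ordered bi-bi rate law and the
#' two leucine inhibition constants of the mixed-inhibition extension.
#' Concentration-type constants are in mM; `vmax` is carried in whatever rate
#' unit the velocities were recorded in (the unit string is an opaque label,
#' echoed through fits and reports, never converted).
#'
#' @param vmax Maximal velocity (> 0).
#' @param ka Michaelis constant for acetyl-CoA (substrate A), mM.
#' @param kb Michaelis constant for alpha-ketoisovalerate (substrate B), mM.
#' @param kia Dissociation constant of acetyl-CoA from the free enzyme, mM.
#' @param kis Slope-associated leucine inhibition constant, mM.  `NA` means
#'   no slope effect (the inhibitor does not bind the free enzyme); the
#'   corresponding factor in the rate law is then exactly 1.
#' @param kii Intercept-associated leucine inhibition constant, mM.  `NA`
#'   means no intercept effect.
#' @param vmax_unit Unit label for `vmax` (not interpreted).
#'
#' @return An object of class `kinetic_parameters`.
#' @seealso [rate_bibi()], [rate_inhibited()], [kib()]
#' @examples
#' p <- kinetic_parameters(vmax = 3.9, ka = 0.026, kb = 0.025, kia = 0.017,
#'                         kis = 0.034, kii = 0.073)
#' p
#' kib(p)
#' @export
kinetic_parameters <- function(vmax, ka, kb, kia, kis = NA_real_,
                               kii = NA_real_,
                               vmax_unit = "mMol min^-1 mg^-1") {
  p <- list(vmax = as.numeric(vmax), ka = as.numeric(ka),
            kb = as.numeric(kb), kia = as.numeric(kia),
            kis = as.numeric(kis), kii = as.numeric(kii),
            vmax_unit = as.character(vmax_unit))
  validate_kinetic_parameters(p)
  structure(p, class = "kinetic_parameters")
}

validate_kinetic_parameters <- function(p) {
  for (nm in c("vmax", "ka", "kb", "kia")) {
    x <- p[[nm]]
    if (length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a single finite positive number", nm),
           call. = FALSE)
  }
  for (nm in c("kis", "kii")) {
    x <- p[[nm]]
    if (length(x) != 1L)
      stop(sprintf("'%s' must have length 1", nm), call. = FALSE)
    if (!is.na(x) && (!is.finite(x) || x <= 0))
      stop(sprintf("'%s' must be NA (absent) or finite and positive", nm),
           call. = FALSE)
  }
  invisible(p)
}

#' Derived inhibition-replot constant Kib
#'
#' The apparent constant that multiplies 1/B in the acetyl-CoA-varied
#' apparent rate law.  It is fully determined by the bi-bi constants,
#' `kib = kia * kb / ka`: this is the unique value for which the apparent
#' law collapses to the ordered bi-bi law at zero inhibitor.
#'
#' @param params A [kinetic_parameters()] object.
#' @return Kib in mM.
#' @export
kib <- function(params) {
  stopifnot(inherits(params, "kinetic_parameters"))
  params$kia * params$kb / params$ka
}

#' @export
print.kinetic_parameters <- function(x, digits = 4, ...) {
  cat("Ordered bi-bi kinetic parameters\n")
  cat(sprintf("  vmax = %s  [%s]\n", format(x$vmax, digits = digits),
              x$vmax_unit))
  for (nm in c("ka", "kb", "kia"))
    cat(sprintf("  %-4s = %s mM\n", nm, format(x[[nm]], digits = digits)))
  for (nm in c("kis", "kii")) {
    cat(sprintf("  %-4s = %s\n", nm,
                if (is.na(x[[nm]])) "absent (no effect)"
                else paste(format(x[[nm]], digits = digits), "mM")))
  }
  invisible(x)
}

#' Inhibition mechanism kinds
#'
#' The four classical reversible inhibition mechanisms distinguished by
#' which apparent constants the inhibitor alters on a double-reciprocal
#' plot: `competitive` (slope only, `kis`), `uncompetitive` (intercept only,
#' `kii`), `noncompetitive` (both, with `kis == kii`), `mixed` (both, free).
#' `none` disables inhibition entirely.
#'
#' @return Character vector of the recognised kind names.
#' @export
inhibition_kinds <- function() {
  c("none", "competitive", "uncompetitive", "noncompetitive", "mixed")
}

#' Check that a parameter set is consistent with an inhibition kind
#'
#' @param params A [kinetic_parameters()] object.
#' @param kind One of [inhibition_kinds()].
#' @return `TRUE` invisibly, or an error describing the inconsistency.
#' @export
check_inhibition_kind <- function(params, kind) {
  kind <- match.arg(kind, inhibition_kinds())
  has_kis <- !is.na(params$kis)
  has_kii <- !is.na(params$kii)
  ok <- switch(kind,
    none           = !has_kis && !has_kii,
    competitive    = has_kis && !has_kii,
    uncompetitive  = !has_kis && has_kii,
    noncompetitive = has_kis && has_kii && params$kis == params$kii,
    mixed          = has_kis && has_kii)
  if (!ok)
    stop(sprintf(
      "parameter set (kis %s, kii %s) is inconsistent with kind '%s'",
      if (has_kis) format(params$kis) else "absent",
      if (has_kii) format(params$kii) else "absent", kind), call. = FALSE)
  invisible(TRUE)
}

#' Reference parameter sets for the K. lactis alpha-IPMS isozymes
#'
#' Point estimates characterizing the two Kluyveromyces lactis
#' alpha-isopropylmalate synthase paralogs, KlLeu4 and KlLeu4BIS: ordered
#' bi-bi constants plus mixed leucine inhibition constants.  These serve as
#' generating truth for the parameter-recovery experiments shipped with the
#' package ([reproduce_reference_table()]).
#'
#' @return A [kinetic_parameters()] object.
#' @examples
#' klleu4_parameters()
#' @export
klleu4_parameters <- function() {
  kinetic_parameters(vmax = 3.864, ka = 0.026, kb = 0.025, kia = 0.017,
                     kis = 0.034, kii = 0.073)
}

#' @rdname klleu4_parameters
#' @export
klleu4bis_parameters <- function() {
  kinetic_parameters(vmax = 2.580, ka = 0.019, kb = 0.055, kia = 0.012,
                     kis = 0.031, kii = 0.090)
}

#' Reference crude-extract IC50 values for leucine, mM
#'
#' Half-maximal inhibitory leucine concentrations measured on whole-cell
#' extracts under the standard assay conditions (0.25 mM acetyl-CoA, 10 mM
#' alpha-KIV), used as generating truth by [run_ic50_recovery()].
#'
#' @return Named numeric vector (mM) with elements `KlLeu4` and `KlLeu4BIS`.
#' @export
reference_ic50 <- function() {
  c(KlLeu4 = 0.020, KlLeu4BIS = 0.037)
}
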