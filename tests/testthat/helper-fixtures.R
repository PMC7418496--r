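# Shared fixtures: the two reference isozyme parameter sets and compact fit
# options used where full multi-start searching is unnecessary.

kl4 <- klleu4_parameters()
kl4bis <- klleu4bis_parameters()

fast_opts <- fit_options(n_starts = 3, seed = 1)

# random parameter draw with Table-2-like magnitudes (log-uniform around the
# reference decade ranges)
draw_params <- function(with_inhibition = FALSE) {
  lu <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  kinetic_parameters(
    vmax = lu(0.5, 10), ka = lu(0.005, 0.1), kb = lu(0.005, 0.1),
    kia = lu(0.005, 0.1),
    kis = if (with_inhibition) lu(0.01, 0.2) else NA,
    kii = if (with_inhibition) lu(0.01, 0.2) else NA)
}

noiseless_grid <- function(params, enzyme = "KlLeu4") {
  simulate_velocity_grid(params, default_grid_design(enzyme),
                         noise_model(0, seed = 1))
}

noiseless_slices <- function(params) {
  simulate_velocity_grid(params, default_inhibition_design(),
                         noise_model(0, seed = 1))
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

log_levels_test <- function(from, to, n) {
  exp(seq(log(from), log(to), length.out = n))
}
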