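---
title: "Ordered bi-bi kinetics, leucine feedback inhibition, and parameter recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordered bi-bi kinetics, leucine feedback inhibition, and parameter recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipmskinetics)
```

## The kinetic model

α-Isopropylmalate synthase condenses acetyl-CoA (A) and α-ketoisovalerate
(B) in a compulsory order — acetyl-CoA binds first — so initial velocities
follow the ordered bi-bi steady-state law

$$v = \frac{V_{max}\,A\,B}{K_{ia}K_b + K_b A + K_a B + AB},$$

with Michaelis constants $K_a$, $K_b$ (mM), the free-enzyme dissociation
constant of acetyl-CoA $K_{ia}$ (mM), and $V_{max}$ in whatever rate unit
the velocities carry (the unit is an opaque label throughout: the package
never converts it, because specific-activity-style units depend on assay
bookkeeping outside the rate law).

Leucine, the end product of the pathway, is a mixed inhibitor: it binds
the free enzyme (weakening apparent substrate affinity; slope effect on a
double-reciprocal plot, constant $K_{is}$) and the substrate-bound
complexes (lowering apparent $V_{max}$; intercept effect, $K_{ii}$). The
package's single generating law multiplies the free-enzyme denominator
terms by $(1 + I/K_{is})$ and the bound-complex terms by $(1 + I/K_{ii})$:

$$v = \frac{V_{max}\,A\,B}{(K_{ia}K_b + K_a B)\,(1 + I/K_{is}) +
  (K_b A + AB)\,(1 + I/K_{ii})}.$$

An absent constant (`NA` in `kinetic_parameters()`) contributes a factor
of exactly 1, i.e. behaves as an infinite constant; this encodes
competitive ($K_{ii}$ absent), uncompetitive ($K_{is}$ absent) and
noncompetitive ($K_{is} = K_{ii}$) mechanisms without sentinel numbers.

### The two apparent forms and the replot constant

Bench work varies one substrate at a fixed level of the other, and the
literature writes the inhibited law in per-slice "apparent" forms. With
acetyl-CoA varied, the apparent form uses a replot constant $K_{ib}$
multiplying $1/B$; the package defines $K_{ib} = K_{ia}K_b/K_a$, the
unique value for which the apparent form is *algebraically identical* to
the full law above (property-tested to 1e-12). With α-KIV varied, the
conventional apparent form (`rate_apparent_varied_b()`) groups the $K_b A$
term with the slope factor instead; it agrees with the full law at $I = 0$
but differs under inhibition. Both groupings are classical; the package
deliberately keeps exactly one self-consistent generating law (the
acetyl-CoA-consistent grouping) for simulation and for the closed-form
IC50, while exposing the α-KIV-varied form for fitting such slices in
their conventional parameterization. This mirrors practice, where the two
slice fits are reported as a single constant set per enzyme.

### Condition-dependent IC50

Because the denominator is linear in $I$, the half-inhibition
concentration at fixed substrates has the closed form
$IC_{50} = (P+Q)/(P/K_{is} + Q/K_{ii})$ with $P = K_{ia}K_b + K_a B$,
$Q = K_b A + AB$. Unlike $K_{is}$/$K_{ii}$ it depends on the assay
concentrations — at the standard crude-extract conditions (0.25 mM
acetyl-CoA, 10 mM α-KIV) the KlLeu4 reference constants give 0.066 mM.
`predicted_ic50()` is verified against bisection on the rate law itself.

## Fitting

All constants are physically positive and span decades, so fits optimize
log-parameters — positivity for free, no constrained solver. Each fit runs
Levenberg–Marquardt (`minpack.lm::nls.lm`, ftol/ptol/gtol 1e-13, max 500
iterations per start) from a heuristic start ($V_{max}^0 = 1.2\max v$;
$K^0$ at the varied-substrate level nearest half-maximal response;
$K_{ia}^0 = K_a^0$; inhibition constants at half the largest inhibitor
level) plus log-uniform jitter of ±1 decade, 10 starts by default, best
RSS wins; everything is deterministic given the `fit_options()` seed, and
observations are fitted in a canonical sort order so estimates are
invariant to row permutation. Standard errors and the covariance come from
the Gauss–Newton approximation (central-difference Jacobian in log space,
delta-method transform to the natural scale) — the familiar "± values" of
kinetic tables.

Inhibition fits are *global*: one shared parameter set across all leucine
levels, never per-curve fits. The default objective is unweighted least
squares, matching the commercial-software convention this workflow
mirrors; `weighting = "inv_v2"` provides the constant-relative-error
alternative. One consequence worth knowing: under proportional noise the
unweighted Gauss–Newton intervals for $V_{max}$ undercover (we measure
~65% instead of 95% at 3% noise), while the matched 1/v² weighting
restores nominal coverage (~92%); the calibration test therefore uses the
matched weighting, and users who believe their error is proportional
should too.

`compare_inhibition_models()` fits the four mechanisms and ranks them by
AICc ($k$ = free parameters + error variance). The mixed fit is seeded
additionally from every converged simpler solution (absent constants set
three decades above the largest inhibitor level), which guarantees the
nested RSS ordering at convergence. If a simpler model comes within 2 AICc
of the minimum, it is reported as best: a near-tie does not justify an
extra constant.

`estimate_ic50()` fits $rel(I) = 1/(1+(I/IC_{50})^h)$ with $h$ fixed at 1
by default — the one-parameter hyperbola, which is exact for purely
intercept-type inhibition at fixed substrates and is the conventional
reporting form; a free Hill slope is available but off by default. An IC50
is only identifiable if the data bracket half-maximal activity, so tables
entirely above or below 0.5 raise an error instead of extrapolating.

### Identifiability

Two limits are intrinsic to the designs, not the optimizer, and both are
surfaced rather than hidden:

* $K_{ia}$ enters only through the small $K_{ia}K_b$ term, so its
  replicate-to-replicate CV at 3% noise is several-fold that of $K_a$
  (asserted in tests; recovery reports carry the caveat, and the
  acceptance bound for $K_{ia}$ is 30% where the others get 10%).
* Under the two-slice inhibition design, the noncompetitive law factorizes
  as $v_{bibi}/(1+I/K)$ and the four bi-bi constants are not jointly
  identifiable (zero-residual fits exist at wrong parameters). Fits flag
  nothing wrong — the RSS is genuinely zero — so the per-mechanism
  round-trip test uses a crossed substrate grid for that mechanism.
  Boundary-escaped estimates (e.g. $K_b$ collapsing when B is effectively
  saturating) are flagged per parameter in `fit_result$boundary`.

## Assay-trace processing

The DTNB-coupled assay reports CoA release as 412 nm absorbance; traces
show a baseline, an exponential burst (Ellman's reagent consuming
contaminant free CoA in commercial acetyl-CoA), then the enzymatic linear
phase. `estimate_initial_rate()` scans 60 s windows after the
preincubation period and accepts the earliest window that is genuinely
linear: R² ≥ 0.98 *and* a curvature gate — the slope change across the
window implied by a quadratic fit must not exceed 2% of the fitted slope.
The gate is what rejects windows still riding the burst tail: a smooth
exponential remnant can carry R² > 0.99 at low noise while biasing the
slope severalfold, so an R² threshold alone is not a linearity test. When
no window qualifies (typical for realistically noisy traces, where a 60 s
window cannot reach R² 0.98 at read noise ~0.002 A), the maximum-R² window
is used and flagged `low_quality`; when even the best window shows no
coherent trend (R² < 0.5, enzyme-free blanks), the slope over the whole
post-preincubation range is reported instead, so blank slopes stay
statistically indistinguishable from zero.

If `preincubation_s` is not given, the burst settling time is detected as
the first time the rolling 30 s slope drops below 5× the final-third
slope; with the curvature gate downstream this recovers burst-trace slopes
to ~2%. Passing the known extract-addition time is still recommended.

`to_specific_activity()` applies Beer–Lambert with ε stored as
14.15 mM⁻¹ cm⁻¹ — numerically the literature NTB²⁻ value of 14,150
M⁻¹ cm⁻¹; assay write-ups sometimes print the mM-based number with
M-based units, so the unit convention is stated explicitly and ε is
configurable. The full unit audit (A/min → mM/min → nmol/min → nmol
min⁻¹ mg⁻¹) is attached to every result.

## The synthetic-data generator

The generator exists so every pipeline stage is testable as a recovery
experiment with known truth. Its defaults are the study conditions:
8×8 log-spaced saturation grids over 0.002–0.1 × 0.002–0.08 mM (KlLeu4)
and 0.008–0.1 × 0.01–0.25 mM (KlLeu4BIS); inhibition slices with
acetyl-CoA varied 0.002–0.06 mM at 0.25 mM α-KIV and α-KIV varied
0.005–0.1 mM at 0.1 mM acetyl-CoA, crossed with leucine at 0, 0.01, 0.02,
0.06, 0.12 mM; dose-response titrations at 0–0.16 mM leucine. Velocity
noise is proportional Gaussian (CV 3% by default — replicate structure and
error magnitudes are rarely reported for this kind of bench data, so this
is a package convention chosen as a typical spectrophotometric
initial-rate CV; 5% for dose-response curves, which add normalization
error), with negative draws redrawn by default; the redraw truncation at
these CVs biases means by far less than 0.5% (property-tested at 10⁴
draws). One seed governs each simulated object, replicate streams are
derived by a counter, and identical configurations produce byte-identical
report files.

What the generator does *not* emulate — and hence what passing recovery
tests cannot certify about real data: substrate depletion and product
inhibition within a trace (true progress curves bend), pipetting
covariance between points on one curve, day effects between replicates,
enzyme instability, and any deviation of the true mechanism from the
ordered bi-bi + linear mixed inhibition family. Recovery results certify
the estimator under the stated error model, nothing more.

## Recovery experiments and problem sizes

`run_parameter_recovery()` / `run_ic50_recovery()` iterate
simulate → fit → aggregate, excluding (and counting) non-converged
replicates, and report per-parameter medians, bias, spread and 95% Wald
coverage; runs with over 20% failures are marked degraded.
`reproduce_reference_table()` runs the canonical noiseless round-trips for both
isozymes (saturation grid → bi-bi fit; inhibition slices → global mixed
fit) and tabulates recovered versus reference values with a 0.1% pass
tolerance — noiseless refits should agree to optimizer precision, and do
(observed ~1e-15).

The shipped experiments use 100 replicates at 3% noise (kinetics) and 100
curves at 5% noise (IC50), sizes at which the medians are stable to well
under the 10% acceptance bands and a full run takes a few seconds on one
CPU. Stochastic acceptance checks use 100 replicates because that is the
declared experiment size, not a truncation.

## Known limitations

* Initial-velocity analysis only: no integrated rate equations, no
  progress-curve fitting.
* The error model menu is Gaussian (proportional + additive); no robust
  losses or variance-function estimation.
* Wald intervals are first-order; profile or bootstrap intervals are out
  of scope (and the $K_{ia}$ caveat shows where Wald is most strained).
* The IC50 hyperbola assumes complete inhibition at saturating leucine;
  partial-inhibition plateaus are not modelled.
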