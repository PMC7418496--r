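# ipmskinetics

Steady-state kinetic analysis of α-isopropylmalate synthase (α-IPMS), the
enzyme catalyzing the first committed step of leucine biosynthesis: the
condensation of acetyl-CoA (A) and α-ketoisovalerate (α-KIV, B), subject to
feedback inhibition by the pathway end product leucine (I). The package is
written for enzymologists characterizing the two *Kluyveromyces lactis*
α-IPMS paralogs, KlLeu4 and KlLeu4BIS, and more generally for anyone
fitting ordered bi-bi rate laws with mixed inhibition to initial-velocity
data.

## The model

Initial velocities follow the compulsory ordered bi-bi steady-state rate
law

v = Vmax·A·B / (Kia·Kb + Kb·A + Ka·B + A·B)

where Ka and Kb are the Michaelis constants of the two substrates and Kia
is the dissociation constant of acetyl-CoA from the free enzyme. Leucine
acts as a mixed inhibitor — it binds both the free enzyme (slope effect,
constant Kis) and the substrate-bound complexes (intercept effect, constant
Kii):

v = Vmax·A·B / [ (Kia·Kb + Ka·B)(1 + I/Kis) + (Kb·A + A·B)(1 + I/Kii) ]

The package provides:

* pure rate-law evaluation, including the two apparent (replot) forms used
  when one substrate is varied at a fixed level of the other, and the
  closed-form condition-dependent IC50 implied by the mixed law;
* global nonlinear least-squares fitting (multi-start Levenberg–Marquardt
  in log-parameter space) of the bi-bi law and of all four classical
  inhibition mechanisms, with Gauss–Newton standard errors;
* AICc-based mechanism selection with a parsimony tie-break;
* hyperbolic / Hill IC50 estimation from relative-activity dose-response
  tables;
* reduction of DTNB (Ellman's reagent) absorbance traces at 412 nm to
  initial rates and specific activities (nmol CoA min⁻¹ mg⁻¹), with
  burst-aware linear-phase selection;
* a fully seeded synthetic-data generator (velocity grids, dose-response
  curves, absorbance traces) and a parameter-recovery pipeline that
  regenerates the reference kinetic table and IC50s as recovery
  experiments.

## Worked example

Simulate a leucine-inhibition experiment for KlLeu4 — the two saturation
slices (acetyl-CoA varied at 0.25 mM α-KIV; α-KIV varied at 0.1 mM
acetyl-CoA) crossed with leucine at 0–0.12 mM, 3% proportional noise — and
fit the mixed-inhibition law globally:

```r
library(ipmskinetics)

d <- simulate_velocity_grid(klleu4_parameters(),
                            default_inhibition_design(),
                            noise_model(0.03, seed = 42),
                            enzyme_label = "KlLeu4")
fit_inhibition(d, "mixed")
#> Kinetic fit: model 'mixed' (law 'full'), 80 observations
#>   rss = 0.06218 | converged: TRUE | starts used: 10
#>   vmax = 4.04 +/- 0.1011
#>   ka   = 0.02816 +/- 0.002218
#>   kb   = 0.02965 +/- 0.004156
#>   kia  = 0.006832 +/- 0.01129
#>   kis  = 0.03166 +/- 0.001927
#>   kii  = 0.07372 +/- 0.005093
```

The generating constants (Vmax 3.864, Ka 0.026, Kb 0.025, Kis 0.034, Kii
0.073) are recovered within roughly one standard error; note the wide
uncertainty on Kia, which enters the rate law only through the small
Kia·Kb term. Mechanism selection confirms mixed inhibition decisively:

```r
compare_inhibition_models(d)$table
#>            model     rss n_params   aicc converged delta_aicc
#> 1          mixed 0.06218        7 -557.2      TRUE        0.0
#> 2 noncompetitive 0.14137        6 -493.9      TRUE       63.3
#> 3    competitive 0.27535        6 -440.6      TRUE      116.6
#> 4  uncompetitive 0.66265        6 -370.3      TRUE      186.9
```

A noisy dose-response curve generated with a true IC50 of 0.020 mM refits
to within its standard error:

```r
estimate_ic50(simulate_dose_response(0.020, noise = noise_model(0.05, seed = 42)))
#> IC50 fit (hyperbolic): 0.02048 mM +/- 0.001326 | hill = 1 | rss = 0.005601
```

And the full noiseless round-trip of the reference parameter table passes
at 0.1% for all twelve parameters:

```r
reproduce_reference_table()
#> Reference-table recovery (noiseless round-trip, tolerance 0.1%)
#>     enzyme parameter reference recovered relative_diff pass
#>     KlLeu4      vmax     3.864     3.864      1.15e-16 pass
#>     ...
#>  KlLeu4BIS       kii     0.090     0.090      1.54e-16 pass
```

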