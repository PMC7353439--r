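# shrinkcore

Shrinking-core analysis of copper ion release from biocidal nanoparticles
and copper-modified thin-film-composite reverse-osmosis (TFC-RO) membranes.

Copper species embedded in a membrane's polyamide layer (Cu-NPs, CuO-NPs,
or an in-situ-formed Cu-oligomer complex) suppress biofouling by releasing
Cu²⁺ ions. This package is for researchers who measure dissolved-ion time
series and CFU growth curves for such systems and want to answer, with
uncertainty quantification:

* **which transport step limits ion release** — liquid-film diffusion,
  diffusion through the porous product shell (or the polyamide layer acting
  as one), or the core-surface reaction;
* **how fast dissolution proceeds** — the effective diffusivity `De` and
  apparent particle number `N0`, or the first-order rate and saturation
  concentration for membrane-complexed copper;
* **how biocidal the membrane is** — the growth-inhibition indicator `I`.

## The model

A spherical particle of initial radius *R* dissolves from the outside in,
leaving a porous shell around a shrinking core of radius *r*(t). With
conversion *X* = 1 − (*r*/*R*)³, each candidate rate-limiting step gives a
closed-form law *t*/τ = *g*(*X*):

| control step | *g*(*X*) | τ (complete conversion) |
|---|---|---|
| core reaction | 1 − (1−X)^(1/3) | ρR / (k_s C_s) |
| porous shell | 1 − 3(1−X)^(2/3) + 2(1−X) | ρR² / (6 D_e C_s) |
| liquid film | X | ρR / (3 k_l C_l) |

The pipeline linearizes transient-phase data as *y* = (1/τ)·*t* through the
origin under each law, selects the regime with the best no-intercept
adjusted R², then fits the selected forward model

C(t) = N₀ ρ (4/3)πR³ w_Cu · g⁻¹(min(t/τ, 1)) / V

for (De, N₀) by MSE minimization, with 95% confidence intervals from the
linearized covariance at the optimum. Membrane-complexed copper is fitted
with the Nernst–Brunner first-order law C(t) = C_sat(1 − e^(−kt)),
k = De·S/(δV). CFU curves yield exponential-phase growth rates μ (slope of
ln CFU over an automatically selected window) and

I(%) = (μ_C − μ_B)/μ_C × 100.

A mixed-control numerical oracle (`ode_oracle()`) integrates the
quasi-steady resistance-in-series model and backs the closed forms in the
tests. Seeded synthetic generators (`gen_dissolution()`,
`gen_growth_curves()`) reproduce the laboratory protocols so the entire
pipeline runs without external data.

## Worked example

```r
library(shrinkcore)

spec <- particle_spec_cu()                       # R = 12.5 nm, rho = 8960 kg/m3
sim  <- gen_dissolution(dissolution_scenario(seed = 42))
ana  <- analyze_dissolution(sim$series, spec, C_s = sim$truth$C_s,
                            sample_name = "Cu-NPs (synthetic)")
ana$step
#> Rate-limiting-step determination (through-origin linearization)
#>          regime slope_inv_tau adjusted_R2 standard_error n_points
#> 1   liquid_film     7.181e-06      0.7474       0.267841        9
#> 2  porous_shell     5.789e-06      0.9998       0.004724        9
#> 3 core_reaction     5.921e-06      0.9713       0.066384        9
#> selected: porous_shell
ana$fit
#> <scm_fit> regime = porous_shell
#>   D_e = 2.354e-11  (±2.25e-12, alpha = 0.05)
#>   N0  = 1.188e+12  (±2.02e+10)
#>   mse = 2.34e-12 (kg/m3)^2, R2 fit = 0.9977, converged = TRUE
```

The linearization identifies porous-shell diffusion as the rate-limiting
step (adjusted R² 0.9998 against ≤ 0.97 for the alternatives — the pattern
seen for copper species both in suspension and in membranes), and the fit
recovers the generating parameters (De = 2.39×10⁻¹¹ m²/s, N₀ = 1.17×10¹²)
within their confidence intervals. The slope 5.79×10⁻⁶ s⁻¹ is 1/τ, i.e.
complete conversion in ≈ 48 h.

```r
gg <- gen_growth_curves(growth_scenario(I_target = 55, seed = 42))
rc <- growth_rate(gg$control); rb <- growth_rate(gg$treated)
inhibition_rate(rc$mu, rb$mu, rc$se, rb$se)$I_percent
#> I = 51.3% +/- 1.5
```

Bacteria near the treated membrane grow at roughly half the control rate —
the >50% inhibition regime reported for copper-modified membranes.

## Analysis workflow

The `analysis/` scripts run the full study end to end on simulated data and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # dissolution + CFU datasets (seeded)
Rscript analysis/02_determine_step.R  # three-regime linearization per sample
Rscript analysis/03_fit.R             # (De, N0) and Nernst-Brunner fits + CIs
Rscript analysis/04_inhibition.R      # growth-inhibition indicator
```

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline from scratch against the
installed package — simulating the suspension experiment, determining the
rate-limiting step, fitting (De, N₀), fitting the Nernst–Brunner saturation
curve, and computing the inhibition indicator — and writes its JSON output:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/scm-core.R` — conversion laws, characteristic times, forward model
* `R/ode-oracle.R` — mixed-control quasi-steady numerical oracle
* `R/step-determination.R` — transient windowing, linearization, selection
* `R/model-fitting.R` — SCM and Nernst–Brunner fits, confidence intervals
* `R/growth-inhibition.R` — growth rates and the inhibition indicator
* `R/synthetic-data.R` — seeded scenario generators
* `R/io.R` — CSV readers/writers, end-to-end analysis, JSON reports
* `vignettes/shrinking-core-dissolution.Rmd` — models, assumptions, design
  choices and limitations in full
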