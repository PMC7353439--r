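---
title: "Shrinking-core analysis of copper ion release: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shrinking-core analysis of copper ion release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrinkcore)
```

## The problem

Copper-based nanoparticles (Cu-NPs, CuO-NPs) and in-situ-formed copper
oligomer complexes give thin-film-composite reverse-osmosis (TFC-RO)
membranes anti-biofouling capacity by releasing toxic Cu²⁺ ions. Designing
such membranes requires knowing *which transport step limits* the ion
release, and *how fast* it proceeds. This package implements that analysis
as a reusable, tested pipeline:

1. a **shrinking core model** (SCM) of particle dissolution with its three
   single-resistance conversion laws and characteristic times;
2. **rate-limiting-step determination** by through-origin linearization of
   transient conversion data, scored with adjusted R²;
3. **nonlinear fitting** of the selected law for the effective diffusivity
   `De` and apparent particle number `N0` (and a Nernst–Brunner first-order
   variant for membrane-complexed copper, which has no countable
   particles);
4. the **growth-inhibition indicator** `I` from CFU curves;
5. a **synthetic-data module** reproducing the protocols, so every stage
   runs and is testable without external data.

## The shrinking core model

A homogeneous sphere of initial radius $R$ dissolves from the outside in,
leaving a porous product shell around an unreacted core of radius
$r_{NP}(t)$. Conversion is the reacted volume fraction

$$X = 1 - \left(\frac{r_{NP}}{R}\right)^3 .$$

(The ratio $\left(r_{NP}/R\right)^3$ itself is sometimes written as the
conversion; that is the *unreacted* fraction, and the conversion laws below
only close for $1-(r_{NP}/R)^3$, which is what the package uses.)

Three serial resistances can limit dissolution. Under a single controlling
resistance, $t/\tau = g(X)$ with

| regime | $g(X)$ | $\tau$ |
|---|---|---|
| core surface reaction | $1-(1-X)^{1/3}$ | $\rho_{NP} R / (k_s C_s)$ |
| porous shell diffusion | $1-3(1-X)^{2/3}+2(1-X)$ | $\rho_{NP} R^2 / (6 D_e C_s)$ |
| liquid film diffusion | $X$ | $\rho_{NP} R / (3 k_l C_l)$ |

All three laws satisfy $g(0)=0$, $g(1)=1$, and are strictly increasing.
Shell control is the slowest early: $g_{shell} \le g_{reaction} \le
g_{film}$ holds for $X \le 0.875$; the shell and reaction curves cross
exactly at $X = 0.875$ (both equal $1/2$ there, which is also a convenient
closed-form test point) and the order of those two reverses afterwards.

The measured quantity is concentration, mapped to conversion as
$X(t) = C(t)\,V/m_0$ — dissolved copper mass over the initial copper mass.
Dissolved-mass-over-initial-mass is the definition consistent with
reporting release as a percentage of initial mass, and it is the package's
fixed convention. Readings above $m_0$ are
possible with measurement noise; conversion clips them at 1 and records an
inconsistency flag rather than failing.

### Mixed control and the numerical oracle

When no single step dominates, the quasi-steady flux through the serial
resistances gives a separable ODE for $r_{NP}(t)$. `ode_oracle()` integrates
the time-to-radius quadrature

$$t(r) = \rho \int_r^R \left[\frac{1}{k_s C_s}
  + \frac{r'^2(1/r'-1/R)}{D_e C_s}
  + \frac{r'^2}{k_l C_l R^2}\right]\, dr'$$

by cumulative trapezoid on a grid uniform in conversion, followed by
monotone (Hyman) spline interpolation — the classical result that the
resistance *times* add. Each term keeps its own driving concentration, so a
single-resistance run reproduces the analytic law and its $\tau$ exactly
(verified to < 1e-4 relative in the tests). One transcription pitfall is
deliberately avoided: the shell-transport flux is sometimes written with
$D_e$ *multiplied* by the shell resistance $(1/r_{NP} - 1/R)$; the standard
quasi-steady form divides by that resistance, and only the standard form is
dimensionally consistent with the shell conversion law, so the oracle uses
it.

An adaptive ODE integrator was considered and rejected: the ODE is
separable, so quadrature plus interpolation is simpler, unconditionally
stable, and equally accurate.

## Rate-limiting-step determination

Each candidate law is linearized as $y_i = g(X_i)$ against $x_i = t_i$ with
**no intercept** — the physical model is $y = (1/\tau)\,x$ exactly, so the
slope is $\sum x y / \sum x^2$. For the no-intercept model the package
defines $R^2 = 1 - \sum(y-\hat y)^2 / \sum y^2$ and
$\bar R^2 = 1 - (1-R^2)\,n/(n-1)$ (one parameter, no intercept). These
definitions are stated because no-intercept R² conventions differ between
software packages; comparisons of the reported tables are only like-for-like
under the same convention.

Only the **transient phase** is linearized; plateau points would bias a
through-origin fit. No universal windowing rule exists, so the package
uses: window end = first sample with $X \ge 0.95 \cdot \max X$
(`plateau_fraction`, configurable). Declining tails — elemental Cu shows a
concentration *decrease* after ~150 h, attributed to re-precipitation under
oxygen depletion — are excluded first, using a running-maximum filter with
tolerance twice the noise SD estimated from the median absolute successive
difference. That estimator deliberately reads the local scatter, not the
trend; on very sparse curves whose point-to-point rise is larger than the
decline of interest, it will not flag the tail, which is acceptable because
sparse tails contribute few points to the window anyway.

The regime with the highest adjusted R² wins; if the top two differ by less
than `tie_tolerance` (default 0.005) the result carries an ambiguity flag
rather than silently choosing. Film and reaction control are genuinely hard
to separate when the transient only covers small $X$ — both laws are nearly
linear there — which is why the recovery guarantees in the test suite
require transient coverage to $X \ge 0.6$.

## Nonlinear fitting

With the regime fixed, the forward model

$$C(t) = \frac{N_0\, \rho_{NP}\, \tfrac{4}{3}\pi R^3\, w_{Cu}}{V}
  \; g^{-1}\!\left(\min(t/\tau, 1)\right)$$

is fitted to the observed concentrations by minimizing the mean squared
error over $(D_e, N_0)$ (or $k_s$/$k_l$ for the other regimes).

**Degeneracy and `C_s`.** The driving concentration enters only through the
product $D_e C_s$ in $\tau$, so the pair is not jointly identifiable. The
caller fixes `C_s` (default 1 kg/m³) and the fitted constant is an
*effective* value absorbing the true solubility — consistent with the field
practice of reporting a single `De`. The synthetic default scenario instead
derives `C_s` from the stated completion time (below), so recovery tests
compare like with like.

**Optimization.** The parameters span orders of magnitude ($10^{-11}$ m²/s
against $10^{12}$ particles), so fitting runs on $(\log D_e, \log N_0)$:
multi-start Nelder–Mead from 5 log-spaced starts around a half-rise-time
heuristic, with a restart polish. On clean data the generating parameters
are recovered to better than 1e-6 relative.

**Confidence intervals.** Default is the covariance method:
$\pm z_{1-\alpha/2}\,\mathrm{SE}$ with $\mathrm{SE}$ from
$\hat\sigma^2 (J^\top J)^{-1}$ at the optimum, $J$ the numerical Jacobian
of the predicted curve. The Jacobian is column-scaled to log-parameter
units before inversion (the raw cross-product is numerically singular at
these magnitudes even though the fit is identifiable) and
$\mathrm{SE}(p) = p\,\mathrm{SE}(\log p)$ by the delta method. A residual
bootstrap is available as `ci_method = "bootstrap"`. The acceptance suite
measures empirical coverage of the 95% interval for `De` at 2%
multiplicative noise: ~94–95% over 200 simulated fits. The noise is
heteroscedastic while the covariance formula assumes homoscedastic
residuals, so coverage holding inside 90–99% is a measured property of this
design, not a theorem.

**Nernst–Brunner.** Membrane-complexed copper has no particle count; its
release follows $C(t) = C_{sat}(1 - e^{-kt})$ with
$k = D_e S/(\delta V)$. The membrane area $S$ and layer thickness $\delta$
are rarely known, so the package fits the lumped $(k, C_{sat})$ and reports
`De` only when the caller supplies the geometry. The saturation value is
reported in mg for a 1 L test volume (numerically equal to mg/L).

## Growth inhibition

$$I(\%) = \frac{\mu_C - \mu_B}{\mu_C} \times 100$$

with $\mu$ the least-squares slope of $\ln(\mathrm{CFU})$ over the
exponential window. $I$ is invariant to the logarithm base (so the choice
of ln over log₁₀ is immaterial), strictly decreasing in $\mu_B$, and
undefined for $\mu_C \le 0$. The window rule is a package design decision: among contiguous windows of ≥ 3 points with log-linear $R^2 \ge 0.98$,
take the largest slope, ties to the longest window; if none qualifies, fall
back to the max-slope 3-point window with a warning. Zero counts are
floored at half the plating detection limit before the log transform, with
a flag. The SE of $I$ is propagated from the two slope SEs by the delta
method.

## The synthetic world

The generators state a world once and keep it; none of their defaults are
tuned against test outcomes.

* **Dissolution protocol**: 2.5 g/L copper loading in 1 L, sampling dense
  within minutes then out to 240 h (`default_schedule("dissolution")`),
  matching the ion-release protocol. Default truth: shell control with
  $D_e = 2.39\times10^{-11}$ m²/s and $N_0 = 1.17\times10^{12}$ — the
  reported suspension fit — with `C_s` derived so that complete conversion
  takes 48 h, the time at which the measured curves reach maximum
  dissolution. Noise is multiplicative Gaussian at CV = 2% (atomic
  absorption scales with signal) with an optional additive floor, and an
  optional post-peak *linear* decline standing in for the re-precipitation
  artifact — a data corruption, deliberately not a mechanism.
* **Conversion basis**: the apparent $N_0$ implies the releasable copper is
  far below the loaded 2.5 g (agglomeration), so by default the generated
  series uses the releasable mass $N_0 m_p w_{Cu}$ as its conversion basis
  — conversion reaches 1, as the linearized transients require. Passing
  `total_copper_g = 2.5` instead gives conversions on the loaded-mass
  basis.
* **Growth protocol**: inoculum $10^7$ CFU/mL, 48 h incubation, lag 4 h,
  $\mu_C = 0.5$ h⁻¹, logistic approach to a carrying capacity of
  $2\times10^9$ CFU/mL, lognormal counting noise CV = 5%, treated rate
  $\mu_B = (1 - I^*/100)\mu_C$. The capacity is a typical aerated-LB
  stationary density; it also controls the curvature bias of the
  exponential-window slope (about $N/K$ over the window), and at $2\times
  10^9$ the automatic window recovers a clean $\mu$ within 2%. A discrete
  lag + logistic was chosen over Baranyi: fewer parameters, same three
  visible phases.
* **Determinism**: every generator takes a seed and restores the caller's
  RNG state; identical scenario + seed gives byte-identical data.

What a green test does **not** establish: the generators produce exactly
the model the fitters assume (plus stated noise), so recovery tests verify
the pipeline's correctness and statistical calibration, not the physical
adequacy of the SCM for real copper suspensions. The real-data phenomena
the generator does not emulate include oxygen-limited redissolution
chemistry (only its shape as a linear decline), particle size
distributions, agglomeration dynamics (only its *effect*, a reduced
apparent $N_0$), and plate-count overdispersion beyond lognormal noise.

## Numerical choices and degenerate inputs

* `invert_g` for the shell law: 64-step bisection on the monotone cubic in
  $u = (1-X)^{1/3}$, accurate to well below 1e-10; closed forms for the
  other regimes.
* Oracle quadrature: 4001-point grid uniform in $X$; single-resistance
  agreement with the closed forms is asserted at 1e-4 but achieves ~1e-7.
* Degenerate inputs error early and specifically: all-zero conversions
  (nothing to linearize), fewer than 3 surviving transient points, zero
  initial mass, non-increasing times, missing kinetic constants.
* Ties in regime selection are reported in enumeration order
  (film, shell, reaction) with the ambiguity flag set.
* The bootstrap with `n_boot = 1` returns a degenerate interval and says
  so, rather than failing.

## Known limitations

* Single-curve fits only; no hierarchical sharing across samples — each
  dissolution curve is an independent experiment.
* No mixed-control *linearization* — the oracle simulates mixed control,
  but step determination considers the three single-resistance laws only.
* The reported `De` is conditional on the assumed `C_s`; absolute
  diffusivities require an independent solubility measurement.
* No modelling of oxygen depletion, Eh/pH, ROS production, or death-phase
  kinetics.
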