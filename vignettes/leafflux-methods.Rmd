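---
title: "Models and estimators in leafflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in leafflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafflux)
library(dplyr)
```

leafflux simulates and analyses the complete measurement chain of a leaf
gas-exchange study: the biochemical photosynthesis model, its coupling to
stomatal and mesophyll CO2 diffusion, and the estimators a practitioner
runs on cuvette logs — Laisk regression, the variable-J mesophyll
conductance method, A–cc and light-response curve fits — together with
the side measurements that calibrate them (cuticular conductance from
drying curves, chamber leak correction, gravimetric whole-plant
transpiration, and stopped-flow CO2-entry kinetics). Because field data
of this kind are rarely redistributable, every input has a seeded
synthetic generator with known ground truth, and the test suite scores
each estimator against that truth.

## The forward model

Net assimilation follows the Farquhar–von Caemmerer–Berry (FvCB) model
at 25 °C. At chloroplastic CO2 mole fraction $c_c$:

$$A_c = \frac{V_{cmax}\,(c_c - \Gamma^*)}{c_c + K_m}, \qquad
  A_j = \frac{J\,(c_c - \Gamma^*)}{4 c_c + 8 \Gamma^*}, \qquad
  A = \min(A_c, A_j) - R_d$$

with $K_m = K_c (1 + O/K_o)$ the effective Michaelis constant. Design
choices, in order of consequence:

* **Hard minimum of the two branches.** No triose-phosphate limitation
  and no hyperbolic smoothing: only $V_{cmax}$ and $J_{max}$ are fitted
  downstream, and a smoothed minimum would leak one branch's information
  into the other's estimate.
* **No temperature responses.** All constants are 25 °C values; the
  simulated cuvette holds the leaf there.
* **$K_m$ constant.** The package ships `km_default = 620.3322`
  µmol mol⁻¹, and `km_chloroplastic()` exposes the closed form. Note a
  documented discrepancy: evaluating $K_c(1+O/K_o)$ with the common
  25 °C constants $K_c = 272.38$, $K_o = 165.82$ and
  $O = 210$ mmol mol⁻¹ gives 617.33, not 620.3322; the provenance of the
  default's final digits is therefore uncertain, but it is kept as the
  conventional constant and is configurable everywhere it enters.

Electron transport saturates with irradiance as the smaller root of
$\theta_J J^2 - (\phi_J I + J_{max}) J + \phi_J I J_{max} = 0$, with
defaults $\theta_J = 0.7$ and $\phi_J = 0.3$ on an incident-photon
basis — standard values for a healthy C3 leaf.

`solve_steady_state()` closes the system against Fick's law: it finds
the $c_c$ where biochemical demand equals diffusive supply
$(c_a - c_c)\,g_{tot}$, with $1/g_{tot} = 1.6/g_{sw} + 1/g_m$ (the 1.6
converts stomatal conductance to water vapour into a CO2 conductance).
The root is bracketed on $[\Gamma^*, c_a + R_d/g_{tot} + 1]$ — the upper
extension covers darkness, where respiration pushes $c_c$ above $c_a$ —
and polished by Brent's method to a supply–demand residual below 1e-9
µmol m⁻² s⁻¹. A parameter set with no root in the bracket raises an
error rather than clamping.

## What the generators emulate

`synthetic_truth()` fixes a leaf: FvCB constants, stomatal and mesophyll
conductances, the apparent photorespiratory compensation point, a flux
noise level, and a seed. Two consistency conventions matter:

* $\Gamma^* = c_i^* + R_d/g_m$. The chloroplastic and apparent
  compensation points are tied through the mesophyll drawdown, so a
  truth specified by $c_i^*$ re-derives $\Gamma^*$.
* Noise is multiplicative Gaussian on the *fluxes* ($A$, $g_{sw}$) only;
  set-points ($c_a$, PAR) are exact, and $c_i$ is recomputed from the
  noisy fluxes the way an analyser derives it. The default cv of 0.02,
  and the 0.5 mg balance noise of the weighing generators, are package
  choices — the measurement protocols state none.

Default designs mirror the measurement programmes: a 17-step A–ci
sequence starting at 400 µmol mol⁻¹ (ascending limb to 2000, then
descending to 50), a 9-step descending light curve from 2000 to 0
µmol m⁻² s⁻¹, and a Laisk family of four sub-curves at PAR
{300, 150, 100, 50} over ca {150, 125, 100, 75, 50}.

The generators do *not* emulate instrument drift, match-valve
artifacts, leaf patchiness, or fluorescence calibration error. Passing
recovery tests therefore demonstrates estimator correctness under the
stated generative model, not robustness to every failure mode of real
instruments.

## Laisk estimation of ci* and Rd

Each sub-curve is fitted by unweighted OLS, $A = a_p + b_p c_i$; the
intercepts are then regressed on the slopes, $a = \alpha + \beta b$,
giving $c_i^* = -\beta$ and $R_d = -\alpha$ (slope–intercept
regression). Negative $R_d$ estimates are flagged, never clamped.

Both FvCB branches vanish at $c_c = \Gamma^*$, so every model curve —
whichever branch limits — passes exactly through $(c_i^*, -R_d)$ in
A–ci space. The estimator is nevertheless *biased* on FvCB-generated
families: the $A_j$ branch is concave in $c_c$, each fitted line is a
chord of a curve, and the extrapolated common intersection drifts. At
the default design and truths ($c_i^* = 38.95$, $R_d = 0.914$,
$g_m = 0.2$) the package measures a bias of about +2 to +3 µmol mol⁻¹
in $c_i^*$ and about −0.3 µmol m⁻² s⁻¹ in $R_d$ — present already at
zero noise, hence structural. This is the known curvature bias of
slope–intercept Laisk analysis; curvature-corrected refinements are out
of scope, so the package reports the estimator as practitioners use it
and exposes an `"idealized"` generator mode (exact lines through the
common point) that isolates estimator algebra from model curvature and
round-trips to 1e-9.

## Variable-J mesophyll conductance

Under RuBP-regeneration limitation the FvCB equation inverts per record:

$$g_m = \frac{A}{c_i - c_i^* \dfrac{J + 8(A+R_d)}{J - 4(A+R_d)}},
\qquad
\frac{\delta C_c}{\delta A} = \frac{12\, c_i^* J}{[J - 4(A+R_d)]^2}$$

$J$ comes either from fluorescence
(`j_from_fluorescence()`, $J = \phi_{PSII} \cdot I \cdot \alpha \beta$
with defaults $\alpha = 0.84$, $\beta = 0.5$) or, under
non-photorespiratory conditions, from gas exchange alone
(`j_nonphotorespiratory()`, $J = 4(A+R_d)$). The sensitivity statistic
$\delta C_c/\delta A$ gates reliability: only records with
$10 < \delta C_c/\delta A < 50$ (strict inequalities — a record at
exactly 10 or 50 fails) pass QC. Records are retained with a reason
code (`below_10`, `above_50`, `singular` at the $J = 4(A+R_d)$ pole,
`nonpositive_gm`); when a record violates the window *and* yields a
nonpositive conductance, the window reason is reported. $R_d$ and
$c_i^*$ enter as pooled constants, with per-record overrides available.

The round-trip convention: simulation-based tests set the estimator's
$c_i^*$ equal to the generating $\Gamma^*$, because the inversion's
compensation point and the forward model's must coincide for the
algebra to close; with that alignment, RuBP-limited noise-free records
return $g_m$ to better than 1e-6 relative.

## Curve fitting

**Light response.** The non-rectangular hyperbola
$A(I) = \frac{\phi I + A_{sat} - \sqrt{(\phi I + A_{sat})^2 - 4\theta\phi I A_{sat}}}{2\theta} - R_d$
is fitted by bounded Levenberg–Marquardt with data-driven starts
($\phi$ from the low-light slope, $A_{sat}$ from the plateau, $R_d$
from the darkest point, $\theta$ over a fixed restart grid); the best
converged restart wins, and $\theta$ pinned at a bound is flagged.
Ordinary least squares in the assimilation direction is the default;
an orthogonal-distance mode (total least squares on axes standardised
by the data's spread) is available for fidelity with
orthogonal-regression workflows, at the cost of needing an error-scale
convention the data cannot supply. Derived quantities:
LCP solves $A(I) = 0$; $A_{sat}$ is reported gross, with
$A_{sat} - R_d$ alongside; the irradiance at 75% of $A_{sat}$ is
defined on the gross rate by default (`I75_gross`), with the net
convention (`I75_net`) always reported too, since either reading of
"75% of saturation" is defensible.

**A–cc curves.** `fit_aci()` converts $c_i$ to
$c_c = c_i - A/g_m$ — a supplied `ci` column always wins over any
pre-existing `cc`, so the conversion cannot be bypassed silently — and
fits $(V_{cmax}, J_{max})$ by Nelder–Mead least squares on the
min-of-branches model with $R_d$, $\Gamma^*$, $K_m$ fixed. With a `PAR`
column the RuBP branch uses $J(I; J_{max})$ per record, so the
recovered parameter is the true $J_{max}$ rather than the realised $J$;
without PAR, light is assumed saturating. If every point falls on one
branch the other parameter is unidentified and is reported as `NA`
with a bound. The `inflection` is the $c_c$ where the branches cross.

**Stopped-flow kinetics.** `fit_exponential_decay()` fits
$F(t) = a\,e^{-kt} + c$ over the first 8 ms (0.125 ms sampling in the
generator), with the start for $k$ from a log-linear pre-fit.
Non-decreasing traces return $k \approx 0$ with a `no_decay` flag
instead of failing, since flat traces are a legitimate negative-control
outcome.

## Leaf water relations and transpiration

`fit_gmin()` turns a post-closure drying curve into the minimum
conductance: OLS mass-loss rate $r$ (g s⁻¹), then
$g_{min} = (r / M_{w}) / (\bar{a} \cdot w)$ with $M_w = 18.01528$
g mol⁻¹, $\bar{a}$ the mean of initial and final single-sided projected
areas, and $w = \mathrm{VPD}/P_{atm}$ the mole-fraction gradient. VPD
uses the Arden Buck saturation vapour pressure. The 1 h stomatal
closure period is a configurable discard window (`discard_s`), default
0 because the weighing protocol starts after closure. One-sided area is
used throughout, following the drying-curve protocol convention;
realistic inputs land in the 5–10 mmol m⁻² s⁻¹ band expected of intact
cuticles.

Chamber leak: in darkness respiration is constant, so the OLS slope of
apparent flux on the ambient-to-chamber CO2 gradient is the gasket
diffusion coefficient $k$ (mol s⁻¹); `apply_leak_correction()`
subtracts $k \,\Delta c / a_{leaf}$ from each record and stamps the
provenance column.

Whole-plant transpiration closes the sealed-pot mass balance
$E = (V + W_i - W_f - FW)/A_t$ (1 ml ≡ 1 g; soil evaporation zero by
the sealed-membrane design). $A_t$ reduces the weekly leaf-area record
by the trapezoidal time-average (m²) by default — each week weighted by
its duration — with a plain-sum mode for compatibility with
cumulative-sum conventions; the reported unit is g H2O per m² of
(time-averaged) leaf area, a convention the package documents because
axis units for such measurements are often left implicit.

## Numerical choices

* Steady-state root: `stats::uniroot`, cc-tolerance 1e-12, residual
  checked < 1e-9; an independent bisection oracle in the test suite
  agrees to < 1e-6 in $A$ over 500 random parameter draws.
* RWC is invariant to shifting or rescaling all three masses (only
  differences enter); tests guard formula typos by perturbing single
  masses instead.
* Nonlinear fits: `minpack.lm::nlsLM` with tight (1e-14/1e-15)
  tolerances and bounded parameters; multi-start grids are fixed, so
  fits are deterministic.
* Exactly-at-bound QC fixtures are constructed from rational
  combinations (e.g. $J = 48$, $A = -1$ gives $\delta C_c/\delta A$
  exactly 10 in floating point), avoiding threshold-rounding
  ambiguity.
* Problem sizes in the recovery tests (e.g. 500 Laisk replicates, 200
  Vcmax replicates, a 1000-point gm grid) were chosen to make
  Monte-Carlo error a small fraction of each tolerance.

## A worked pipeline run

```{r pipeline}
report <- run_pipeline(list(scenario = list(seed = 1)))
report
glance(report$laisk)
report$gm_records |>
  count(reason)
```

The synthetic A–ci curve spans both FvCB branches, so a sizeable share
of records legitimately fails the $\delta C_c/\delta A$ window —
mirroring field practice, where the variable-J method is trusted only
in its mid-range. Exclusions are logged per record with reasons; raw
records are never dropped.

## Known limitations

* The Laisk estimator's curvature bias (above) is reported, not
  corrected.
* The variable-J estimator assumes RuBP limitation; on Rubisco-limited
  records it returns a biased conductance that the
  $\delta C_c/\delta A$ window only partially screens out. Pooled gm
  from a full A–ci curve therefore understates the true value; per-gm
  working-range checks use RuBP-limited simulations.
* No temperature or CO2 acclimation, no C4 pathway, no leaf energy
  balance.
* The orthogonal-distance light-curve mode standardises axes by the
  sample spread; with a known instrument error ratio a user should
  rescale accordingly.
```
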