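---
title: "Estimating under-5 and neonatal mortality from incomplete sources: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating under-5 and neonatal mortality from incomplete sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind `sdgmort`, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design choices
made where several reasonable options existed.

## 1. The estimation problem

Province-level child mortality must be assembled from sources with different,
partly unknown error structures:

* **Death registration (DRS).** Counts of registered under-5 and neonatal
  deaths per province-year. Registration is *incomplete*: only a fraction
  $c_{p,t} \in (0,1]$ of true deaths is recorded, and that fraction is not
  observed. The registered rate is therefore biased low by roughly the factor
  $c$.
* **Summary birth histories (SBH).** Census/survey counts of children ever
  born (CEB) and children dead (CD) per 5-year maternal age group. These are
  converted to time-located 5q0 estimates by indirect (Brass-type)
  multipliers.
* **Complete birth histories (CBH).** Per-child records of birth date and
  survival, converted to direct occurrence/exposure estimates.

All estimates are expressed as deaths per 1,000 live births; all modeling is
on the natural-log scale.

## 2. Data quality gate

A candidate dataset enters the analysis only if the missing-value fraction of
its key variables is at or below a cutoff (default 0.10, configurable in
$[0.05, 0.10]$) *and* its boys-to-girls sex ratio lies in $[1.00, 1.06]$,
both bounds inclusive. `qc_gate()` errors rather than silently accepting when
either statistic is missing. The inclusive-boundary convention means a
dataset exactly at the cutoff passes.

## 3. Birth-history estimators

**Direct (CBH).** For a calendar year, the occurrence/exposure rate is
$m = D / E$, weighted deaths under 60 months over weighted person-years of
under-5 exposure. The reported value is the probability-type
$5q_0 = 1000\,(1 - e^{-5m})$, using the constant-hazard identity. The source
data determine only the rate quotient; the conversion makes the direct
estimates commensurate with the 5q0-type quantities from the other sources,
and `conversion = "none"` is available to report $5000\,m$ instead. The design
variance is the weighted-Poisson approximation $1/D$, with a $+0.5$
continuity correction when no deaths are observed (a zero-death year reports
a value of zero and a variance from 0.5 deaths; the log-scale stage models
drop zero values, which is why survey sizes in the fixtures are chosen large
enough to make zero-death cells rare — see §8).

**Indirect (SBH).** The cohort route (`mac_estimate()`) converts each
maternal-age-group ratio CD/CEB into $1000 \cdot \text{CD/CEB} \cdot k_i$,
referenced to $t_\text{survey} - \tau_i$; the period route (`map_estimate()`)
pools the same ratios into 5-year period buckets with CEB weights. The
multipliers $k_i$ and offsets $\tau_i$ form a pluggable `CoefficientSet`
because no single set is canonical:

* `brass_coefs()` — classical illustrative values;
* `identity_coefs()` — unit multipliers, for testing the mechanics;
* `calibrated_sbh_coefs()` — multipliers derived by numerical integration
  from the generator's own fertility and exposure assumptions
  ($k_i = 1/\mathbb{E}[G(a)]$, where $G(a)$ is the fraction of under-5 risk
  experienced by age $a$), the analogue of deriving coefficients from a model
  life table. The parameter-recovery tests use this set, so the indirect
  estimators are tested against a truth they are actually consistent with.

The youngest maternal age group (15–19) is excluded by default: its parities
are tiny, its multiplier is the largest, and the resulting estimates are
dominated by zero-truncation selection noise — the standard reason this group
is discarded in practice.

## 4. Stage model 1: Gaussian-process regression

The mean function is the weighted mixed model
$\log y \sim \text{covariates} + (1\,|\,\text{province})$ fit by `lme4`
(inverse-design-variance weights; constant covariate columns are dropped with
a message; genuinely collinear columns are an error naming them). The GP then
models residual structure:

$$ y_i = \mu_{p_i,t_i} + f_{p_i,t_i} + \log c_{s_i}\,[\text{adjustable}] + \varepsilon_i,
\qquad f \sim \mathcal{GP}\!\left(0,\ a^2\, K_\text{space} \otimes K_\text{time}\right), $$

with $\varepsilon_i \sim N(0, v_i + \sigma^2_{s_i})$. Parameters and
defaults:

| parameter | default | meaning |
|---|---|---|
| `matern_smoothness` | 1.5 | Matérn $\nu$ of the time kernel (once-differentiable trends) |
| `length_scale_time` | 5 years | decorrelation scale of the time trend |
| `spatial_kernel` | adjacency-diffusion | heat kernel $e^{-\theta L}$ on the graph Laplacian, normalized to a correlation; `exchangeable` available |
| `spatial_theta` | 0.7 | diffusion time (larger = spatially smoother) |
| `amplitude_sd` | 0.3 | prior scale of the GP amplitude on the log-rate scale |
| `completeness_prior` | Beta(6, 2) | shared completeness per adjustable source (prior mean 0.75) |
| `nonsampling_sd_prior` | 0.12–0.15 | half-normal scales per source |

The space-time covariance is *separable* because only the temporal component
has a stated functional family; the spatial factor is an explicit, switchable
choice. Completeness is modeled as a single Beta-distributed value per
source, entering as an additive $\log c$ offset: the data identify it through
the level contrast between registration and the unbiased birth-history
sources, which is why the pipeline always feeds all sources to this model.
Neonatal registration uses the under-5 completeness as a proxy — the
registration data themselves cannot identify a separate neonatal
completeness.

Inference is blocked Gibbs/Metropolis MCMC. Both stage models have Gaussian
likelihoods on log rates, so the latent-field conditional is an *exact*
multivariate normal (one Cholesky per sweep), the amplitude is conjugate
inverse-gamma, and completeness and the non-sampling SDs take random-walk
Metropolis steps (logit and log scales). Two chains are run by default and a
split-type potential-scale-reduction diagnostic over probed cells warns above
1.05 — a warning, never a silent success. `method = "map"` freezes the
hyperparameters at their prior centers and draws the field exactly: a
deterministic, fast route for smoke tests and for limit checks
(interpolation, completeness offset algebra).

## 5. Stage model 2: spatiotemporal BYM + RW2

$$ \log r_{p,t} = \alpha + s_p + u_p + g_t + h_{p,t}, $$

with $s$ an intrinsic-CAR (Besag) structured effect, $u$ an unstructured
province effect, $g$ a second-order random walk (penalizing second
differences, so linear time trends are free), and $h$ independent
province-year interaction (the simplest Knorr-Held interaction type; the
type is exposed as configuration). All precisions carry conjugate Gamma
priors; $s$ and $g$ are constrained to sum to zero.

Design choices:

* **Scaled Besag.** The structured precision is scaled so the constrained
  field has geometric-mean marginal variance 1 at unit precision (the same
  scaling used by the modern BYM2 parameterization). The full BYM2
  mixing-parameter form was not used because it breaks conjugacy; the scaled
  Besag + iid pair keeps the scaling benefit with exact Gibbs conditionals.
* **Constraint handling.** The unconstrained joint precision is singular
  (the CAR and RW2 levels are unidentified against the intercept and each
  other); a $10^{-6}$ ridge makes it proper and draws are corrected to the
  constraint subspace by conditioning-by-kriging. A graph that is
  disconnected would leave the precision singular even then, and is an error.
* **Observation noise.** The likelihood is normal on log rates with design
  variance, matching the GPR module so the ensemble compares like with like,
  plus a fixed `obs_nugget` (default 0.015 on the log-variance scale) that
  plays the role of the non-sampling variance the GPR estimates. Without it,
  with one observation per cell, the interaction term chases observation
  noise and the intervals undercover.
* **Registration inputs.** This stage has no completeness parameter; the
  pipeline passes DRS values divided by the GPR posterior-mean completeness,
  and the ensemble scoring corrects held-out DRS values the same way.

Inference is blocked Gibbs (every conditional conjugate), or
`method = "laplace"`: an empirical-Bayes mode-finding loop with exact
Gaussian draws around the mode, used for deterministic equivalence tests
(the mode provably solves the corresponding penalized least-squares problem,
and the test suite checks this against an independent KKT-system solve).

## 6. Ensemble averaging

20% of DRS observations and 20% of all others are held back
(`make_holdout()`, seeded, per-stratum counts within one observation of the
target fraction). Models are scored on the held-out points by log-scale RMSE
against the posterior median — DRS test values completeness-corrected first —
and by 95% empirical coverage. Ranking is by RMSE with
$|\text{coverage} - 0.95|$ as tie-break; a rank-sum combination of both
metrics is available (`ranking = "rank-sum"`) since the two metrics admit
either reading. Weights decline monotonically in rank:
$w_k \propto K - \text{rank}_k + 1$ by default, $e^{-\lambda\,\text{rank}}$
as the alternative; both are tested. The combined posterior is the mixture:
each output draw comes from model $k$ with probability $w_k$ (checked
against a brute-force pooled-draw oracle in the tests). RMSE is computed on
the log scale because both stage models operate there.

## 7. The NMR relation

Pooled across province-years, $\log \text{NMR}$ is quadratic in
$\log \text{U5MR}$; province-year effects $\delta_{p,t}$ absorb deviations.
The quadratic is fit by weighted least squares of completeness-corrected
registration NMR on the posterior-median log U5MR; its residuals are
smoothed by the GP engine (zero-mean) and the spatiotemporal engine,
combined by the ensemble machinery. Final draws propagate all three
uncertainty sources: each output draw pairs a U5MR posterior draw, a normal
draw of the quadratic coefficients, and an effect-surface draw, and is
truncated at its paired U5MR draw ($\log$-scale clipping), making
NMR ≤ U5MR a hard, draw-wise invariant. An observation above its paired
U5MR median triggers a warning, not a failure — the truncation handles it.

## 8. The synthetic generator

`generate_truth()` draws the latent surfaces from the same ingredients the
models assume:

$$\log \text{U5MR} = \beta_0 + \beta^\top x_{p,t} + s_p + g_t + h_{p,t}, \qquad
\log \text{NMR} = b_0 + b_1 \log \text{U5MR} + b_2 (\log \text{U5MR})^2 + d_{p,t},$$

with $s$ scaled-ICAR, $g$ RW2, $h, d$ iid normal, and NMR truncated at U5MR.
Observable sources are then generated: binomial registered deaths thinned by
completeness (expected registered rate = completeness × true rate, checked
against the binomial mean in the tests), SBH tables by exposing each
simulated birth to the cumulative risk fraction $G(a) = \min(a/5, 1)^{0.4}$
of its cohort, and month-resolution CBH records from a piecewise-constant
hazard whose first month carries the full neonatal risk.

Default fixture conditions (8 provinces on a grid, 2 regions, years
2005–2017, seed 20170101):

* `mean_coefs = (3.0, −0.15, −0.10, −0.10)`: baseline rates near
  $e^3 \approx 20$ per 1,000 with mildly protective standardized covariates.
* `spatial_sd = 0.15`, `interaction_sd = 0.05`, `obs_sd = 0.05`: moderate
  spatial heterogeneity and cell-level noise on the log scale.
* `temporal_sd = 0.01` (RW2 innovation SD). RW2 innovations are *second
  differences*, so their effect compounds quadratically: 0.01 per year
  accumulates to roughly ±0.2 on the log scale over 13 years, a realistic
  deviation-from-trend; an order larger would imply rate swings of a factor
  of two that no covariate could explain and would dominate the panel.
* `completeness_range = (0.6, 0.95)`, drawn i.i.d. per province-year
  (`constant` per-province option available, since the time structure of
  registration completeness is not established). Published sources document
  only a >50% incompleteness bound for the early registry years; this range
  is a documented stand-in for the modern-era registry.
* `births_per_province_year = 20000` with ±15% province variation.
* Survey sizes in fixtures: 400 mothers per province-age-group (SBH),
  1,200 mothers per province (CBH). These are census/DHS scales; they also
  keep zero-death cells (which cannot enter a log-scale model and whose
  omission would bias the anchors upward) rare.
* `nmr_quad_coefs = (−0.7, 1.0, 0.03)`, giving a neonatal share of under-5
  mortality around 65–75%, `nmr_effect_sd = 0.05`.

What the generator does *not* emulate: real fertility schedules and census
sampling designs (a fixed parity vector is used — only the CD/CEB → mortality
mapping is under test); migration; age-misreporting and heaping; the excluded
poor-quality sources beyond an optional high-missingness summary for QC
tests; and cause-of-death structure. A passing recovery suite therefore
demonstrates that the pipeline inverts its own assumed data-generating
process at realistic noise levels — not that those assumptions hold for any
particular country's registries.

## 9. Numerical choices and degenerate inputs

* Zero/negative rate values cannot enter log-scale models; they are dropped
  with a warning (and continuity corrections upstream keep them rare).
* Rates are clipped to $(10^{-4}, 999.9)$ on exponentiation; the
  `rate_surface` container enforces $(0, 1000)$.
* Eigenvalues of kernel matrices are floored at $10^{-8}$; intrinsic
  precision blocks carry a $10^{-6}$ ridge ahead of constraint correction.
* Ties in ranking break by $|\text{coverage} - 0.95|$, then model tag; ties
  in reporting ranks break by area label.
* SDG achievement uses `rate ≤ threshold` with a $10^{-9}$ numerical guard;
  the reporting count of provinces *above* target uses a strict `>`
  (a province exactly at the threshold has achieved it).
* Reporting tables round to one decimal only in dedicated display columns;
  all internal arithmetic is full precision. Death counts are rounded
  half-up at reporting only.
* Fractional reference years (indirect/direct estimates) are matched to the
  nearest panel year for model indexing.

## 10. Problem sizes used by the test suite

The recovery programme runs the full ensemble on the default fixture — two
SBH surveys, one CBH survey, and the 13-year registration panel — with
2-chain Gibbs at 100 warmup / 75 kept sweeps per chain, 200 independent
replicates for the coverage criterion and 20 for the variance-component
recovery. These sizes give Monte-Carlo error comfortably below the margins
being tested (the combined-surface coverage criterion, ≥ 90%, is typically
met at 92–93%) while keeping a full run of the suite in single-digit
minutes on one CPU. Production analyses should raise `warmup`/`draws`
severalfold; the diagnostics warn when chains disagree.

## 11. Known limitations

* The MAC/MAP coefficient values are the largest acknowledged gap: the
  classical default set is illustrative, and serious use requires
  coefficients matched to the population's fertility and mortality pattern
  (via `read_coefs()` or `calibrated_sbh_coefs()`-style derivation).
* Completeness is a single shared parameter per source; per-cell completeness
  variation is absorbed into non-sampling variance rather than modeled.
* The ST stage depends on the GPR stage for its completeness correction; the
  two stages are not jointly identified from registration data alone.
* Scenario projections are point trajectories (the scenario definitions are
  deterministic transforms of point AARRs); probabilistic projection bands
  are out of scope.
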