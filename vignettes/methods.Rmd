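---
title: "Estimating district maternal mortality and assessing cash-transfer impact: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating district maternal mortality and assessing cash-transfer impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(jsyimpact)
```

## The problem

Janani Suraksha Yojana (JSY) is India's conditional cash-transfer program
paying women who deliver in a health facility, with the ultimate aim of
reducing maternal mortality. Whether the observed surge in institutional
delivery translated into fewer maternal deaths is an empirical question that
must be answered from fragmentary evidence: no Indian state holds a clean
district-by-year series of maternal deaths. What exists is a patchwork of
sources — vital statistics, health-department bulletins, national surveys —
each reporting at a different geographic level (district, division, or
state), each with its own under- or over-reporting bias, and each with gaps.

`jsyimpact` implements a two-stage cascade for this situation:

1. **Stage 1** synthesises all sources into a Bayesian hierarchical
   negative-binomial model and produces a complete posterior distribution
   over the district-by-year maternal mortality ratio (MMR, deaths per
   100,000 live births).
2. **Stage 2** regresses log-MMR on program exposure in a multilevel model
   with district-specific random slopes — fitted not once but to each of
   many posterior MMR draws, with coefficients pooled across draws so that
   stage-1 uncertainty propagates honestly into the impact estimates.

Because the motivating administrative data are not publicly deposited, the
package ships a synthetic-data generator with known ground truth. The
generator is first-class code: every inferential claim the package makes is
validated against scenarios whose true MMR surfaces, source biases, and
program effects are known exactly.

## Stage 1: the hierarchical MMR model

For district $d$ in year $t$, the latent mortality level is

$$\log \mathrm{MMR}_{d,t} = X_d\beta + \alpha_d + \zeta_d\,(t - \bar t) + \xi_{d,t},$$

with covariates $X_d$ (total fertility rate and human development index,
both centred), a district intercept $\alpha_d$, a district linear trend
$\zeta_d$, and a smooth non-linear perturbation $\xi_{d,t}$. Both
$\alpha_d$ and $\zeta_d$ are nested: districts draw around division means,
divisions around state means. The nesting is hierarchically *centred*
($\alpha_d \sim N(a_{v[d]}, \sigma^2_{\alpha})$,
$a_v \sim N(b_0, \sigma^2_{a})$) rather than expressed as zero-mean
offsets; the two parameterisations define the same model, but centring
removes the additive redundancy between the intercept and the random-effect
locations and mixes far better.

A source $s$ reporting death counts at geographic level $\ell$ observes

$$y_{u,t,s} \sim \mathrm{NegBin}\!\left(\mu = e^{\delta_s}
  \sum_{d \in u} \mathrm{MMR}_{d,t}\, B_{d,t}/10^5,\; r\right),$$

where $B_{d,t}$ are live births (the exposure), the sum runs over the
districts composing the reporting unit $u$, $\delta_s$ is a source-specific
log-bias, and $r$ is the negative-binomial size (overdispersion) parameter.
One designated reference source — by default the source reporting at the
highest geographic level, i.e. the survey-class "gold standard" — has
$\delta = 0$; all other biases are estimated relative to it. Sources that
publish MMR estimates rather than counts enter through a lognormal
observation model with a source-level residual sd.

Design choices worth knowing about:

* **Non-linear trend.** $\xi_{d,t}$ follows a second-order random walk
  across years with a shared innovation sd. The first two years are anchored
  at zero, which removes the random walk's intrinsic level and slope and
  leaves a purely non-linear component; without the anchor the walk is
  confounded with $\alpha_d$ and $\zeta_d$.
* **Counts, not rates, in the likelihood.** Division- and state-level
  records constrain the *sum* of member districts' expected deaths, which
  is how envelope information enters the fit coherently.
* **Sampler.** The joint posterior is sampled with JAGS (Gibbs/Metropolis),
  2 chains by default, with the negative binomial expressed as its
  Poisson–Gamma mixture. All chains are seeded deterministically, so a fit
  is reproducible bit-for-bit. Convergence is assessed by split-chain
  Gelman–Rubin $\hat R$ on the structural parameters; a fit with
  $\max \hat R \ge 1.1$ is *flagged*, never silently accepted.
* **Priors** (all overridable): $b_0 \sim N(\log 300, 1)$ — weakly
  informative on the plausible MMR range for a high-burden Indian state;
  covariate effects $N(0, 2^2)$; source effects $N(0, 1)$; hierarchical
  sds uniform on $(0, 1)$ (trend-slope sds on $(0, 0.2)$); dispersion
  $r \sim \mathrm{Gamma}(2, 0.1)$.
* **Summaries.** Medians and 2.5–97.5% quantiles are computed on the log
  scale and exponentiated, so interval summaries commute exactly with the
  log transform. Predictions exclude $\delta_s$: they estimate the latent
  true MMR, not any source's reported level.

### Model checking

`compute_cpo()` scores leave-one-out predictive validity with conditional
predictive ordinates. Two routes are provided and cross-checked: the
harmonic-mean identity on the full fit's draws
($\mathrm{CPO}_i^{-1} = E_{\text{post}}[1/p(y_i\mid\theta)]$), and exact
refits without each observation. The harmonic-mean estimator is famously
unstable when the inverse-likelihood weights have heavy tails, so an
observation is flagged when its weight ESS falls below 100, *or* below
2.5% of the total draw count (with long chains an absolute floor stops
detecting degeneracy), *or* when the Hill estimate of the weights' Pareto
tail index exceeds 0.7 — the standard cutoff beyond which
importance-sampling estimates stop being trustworthy, and the diagnostic
that catches heavy tails hiding behind a respectable ESS. Flagged
observations fall back to exact refits. `compare_models()` ranks competing
specifications (covariates on/off, non-linear trend on/off, source effects
on/off) by the sum of log CPO, excluding non-converged fits.

## Stage 2: draw-propagated impact regression

For exposure $E_{d,t}$ — either the JSY-supported share of all deliveries
(`jsy_prop`, on 0–1) or annual JSY expenditure in lakh (`expenditure`,
never rescaled) — each posterior MMR surface is fitted with

$$\log \mathrm{MMR}_{d,t} = \beta_0 + \beta_1\,\mathrm{Urban}_d +
\beta_2\,\mathrm{Lit}_d + \beta_3\,\mathrm{ANC3}_{d,t} +
\beta_4\,\mathrm{NJSY}_{d,t} + \beta_5 E_{d,t} +
\alpha_t + \eta_d + \varphi_d E_{d,t} + \varepsilon_{d,t},$$

with a year random intercept $\alpha_t$, district random intercept
$\eta_d$, and district random exposure slope $\varphi_d$ (independent of
$\eta_d$ by default). Percentages (urban, literacy, ANC3) stay on the
0–100 scale and proportions on 0–1, so the coefficient magnitudes are
directly interpretable per unit of each variable. Each single fit uses
REML via `lme4` with a fixed optimizer (bobyqa, no derivative
re-evaluation), so fits are deterministic; singular variance components are
kept at the boundary and counted, not hidden. With an empty random-effects
specification the model collapses to ordinary least squares — a limit used
by the test suite against hand-rolled normal equations.

Fitting the model to $m$ posterior surfaces yields $m$ coefficient vectors,
pooled with Rubin-style rules: the pooled estimate is the mean of per-draw
estimates, and the pooled variance is the mean within-draw variance plus
$(1 + 1/m)$ times the between-draw variance, with intervals and p-values
from the normal reference distribution. The empirical 2.5/97.5 percentiles
of the per-draw estimates are reported alongside as a distribution-free
check. District total slopes $\beta_5 + \varphi_d$ are pooled identically,
and a district is called "significant" when its pooled 95% interval
excludes zero. More than 5% of draws failing to fit aborts the analysis
with a diagnostic rather than quietly pooling the survivors.

## The synthetic-data generator

`scenario_config()` defaults describe a scaled-down version of a large
central-Indian state over 2005–2010:

* 12 districts in 3 divisions (the full 50-district, 10-division scale is
  one argument away), 1.5 million people per district, crude birth rate 26
  per 1,000, stillbirth rate 15 per 1,000 births.
* Baseline MMR 350 with a mild downward linear trend (mean −0.007/year on
  the log scale, district sd 0.012) plus an RW2 non-linear wobble, so that
  the state-level decline over the six years is on the order of 10–12%.
* Institutional delivery rising from 23.9% to 55.9% of births and the JSY
  share of institutional deliveries from 14% to 80%, interpolated on the
  logit scale with per-district offsets; the true program effect on
  log-MMR defaults to −0.223 per unit of JSY delivery proportion.
* Three reporting sources: two district-level administrative sources with
  multiplicative biases 0.85 and 0.70 and coverage 0.90/0.95, and an
  unbiased state-level survey-class envelope. Administrative counts use a
  negative-binomial size of 30; the envelope source is near-Poisson
  (size 500), reflecting that a "gold standard" series is precise at its
  aggregate scale — an envelope as noisy as the district sources would
  carry no benchmarking information.
* A Health-Bulletin-like program panel whose institutional-delivery
  proportions are over-reported by a fixed per-district factor: the implied
  survey/bulletin correction factors are drawn as
  $0.34 + 0.63\,\mathrm{Beta}(3,4)$, spanning 0.34–0.97 with mean exactly
  0.61. A survey benchmark reports the *true* proportion for one year
  (2007 by default), from which `derive_correction_factors()` recovers the
  factors. Reported proportions are capped at 0.97, so in
  heavily-inflating districts the correction is attenuated — deliberate
  realism: the recoverable signal saturates where over-reporting meets the
  ceiling.
* Expenditure is 0.014 lakh per JSY delivery times a 1.3 overhead factor
  with 5% lognormal noise, which puts district-year budgets in the
  10²–10⁴ lakh range and per-lakh regression coefficients on the 10⁻⁶
  order.

One master seed spawns fixed substreams for truth, observations, and the
program panel, so adding a source or switching panel options never perturbs
the truth tables. What the generator does *not* emulate: spatial
autocorrelation beyond the division nesting (the estimation model makes no
adjacency assumption either), fiscal-year reporting offsets, migration,
and multiple births. Passing tests on this generator therefore show that
the machinery recovers truth under the *stated* data pathologies — biased,
incomplete, multi-level, over-reported sources — not that it cures every
defect of real administrative data.

## Harmonization choices

* **Envelope benchmarking** is proportional raking: within each (envelope
  unit, year), district counts are scaled by one factor so they sum to the
  envelope exactly. It is applied division-first, then state, when both
  exist (order configurable). A zero-sum group under a positive envelope
  splits equally — a deterministic, documented fallback. In the pipeline
  the whole step is optional: with source effects in the likelihood, the
  model itself calibrates sources to the reference, and pre-benchmarking
  mainly matters when the downstream model is fitted without $\delta_s$.
* **Correction factors** above 1 (survey exceeding bulletin) are allowed
  with a warning rather than capped: the published 0.34–0.97 range is an
  empirical observation, not a rule. Corrected proportions above 1 are
  clipped, with a warning. Factors apply constantly across years — the
  identifying assumption, since only one survey year exists.

## Numerical conventions and simulation sizes

Headline percent changes round to the nearest integer; district tables use
one decimal. Coefficient tables print three decimals, switching to
scientific notation for interval bounds that would round to 0.000, and
p-values that round to zero print as "0".

The validation suite runs at sizes chosen to give each check statistical
teeth while staying desk-sized: stage-1 interval coverage over 20
replicated default scenarios (400 kept draws × 2 chains each); CPO
cross-validation on a 12-observation instance with 6,000 draws per chain;
null calibration of the exposure test over 100 replicates of 50 pooled
surfaces (log-scale spread 0.10, a typical stage-1 posterior width at the
default scenario size); power against a −0.6 effect over 20 replicates at
the full 50-district scale with spread 0.02 ("low stage-1 noise") —
detection power at the 12-district default is intrinsically limited, not by
stage-1 noise but by the collinearity of JSY and non-JSY delivery growth,
which is exactly the small-sample pathology the full-scale study design
avoids; and propagation monotonicity comparing spreads 0.10 vs 0.40 over
20 replicates.

## Known limitations

* The ambiguous nesting notation of mixed-level sources is resolved as
  source-independent latent district effects plus an additive source
  effect; alternatives (source-specific trends) are not implemented.
* Direct-MMR sources without denominators use a lognormal observation
  model; converting them to pseudo-counts requires the reported
  denominator.
* Stage 2 is associational. No instrument, no difference-in-differences:
  a district-level confounder moving with JSY uptake would bias
  $\beta_5$, and the package makes no claim otherwise.
* Calendar years are assumed throughout; fiscal-year sources must be
  mapped before ingestion.
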