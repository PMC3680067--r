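---
title: "Embryo-Uterus models: likelihood, inference strategies and sub-model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embryo-Uterus models: likelihood, inference strategies and sub-model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eumodel)
```

## The model and its assumptions

An IVF treatment cycle $i$ transfers $n_i$ embryos, but only the number of
implantations $k_i$ is observed — individual embryos cannot be tracked
after transfer. The Embryo-Uterus (EU) model resolves this partial
observability with a mechanistic two-level structure: embryo $j$ of cycle
$i$ develops if and only if it is viable (probability $e_{ij}$) and the
uterus is receptive (probability $u_i$). Both components are logistic
sub-models in covariates,
$$\operatorname{logit} u_i = \tilde\beta_U' U_i, \qquad
  \operatorname{logit} e_{ij} = \tilde\beta_E' E_{ij},$$
and the observed count follows
$$P_{ik} = (1-u_i)\,\delta(k) + u_i \sum_{|s|=k}\ \prod_j
  e_{ij}^{s_j}(1-e_{ij})^{1-s_j},$$
the sum running over all subsets of $k$ of the $n_i$ embryos (a
Poisson-binomial mass multiplied by the receptivity probability, with the
whole $k=0$ atom of an unreceptive uterus added via $\delta$).

The assumptions are strong and should be kept in mind: conditional on
covariates, embryo viabilities are mutually independent and independent of
uterine receptivity, and cycles are independent (one cycle per couple;
repeat-cycle random effects are out of scope here). The "uterus" component
in practice absorbs any cycle-level success factor, not only literal
receptivity.

Identifiability of the *split* between the two sub-models comes from the
twin rate: with only single-embryo transfers, the data inform only the
product $u \cdot e$, and the observed information becomes singular along
that ridge. `eu_fit()` detects this (condition number of the observed
information above `cond_warn = 1e8`) and warns rather than fails, since
such data are statistically rather than programmatically degenerate.

## Fitting

`eu_fit()` maximises the exact log-likelihood $\sum_i \log P_{i,k_i}$ by
BFGS on the unconstrained coefficient scale with an analytic gradient
(both implemented in C++), followed by Newton polishing steps on the
finite-differenced observed information until the gradient norm is below
`gtol = 1e-8`. Near the optimum a Newton step changes the likelihood by
less than floating-point rounding, so polishing steps are accepted on
gradient-norm descent instead of likelihood increase. The fit is
deterministic: refitting the same data gives bit-identical results.

Numerical choices:

* Probabilities are computed in direct (not log) space; the subset sum is
  enumerated exactly. `eu_kfold_probability()` enumerates subsets up to a
  cap of 10 embryos and switches to an equivalent dynamic-programming
  convolution beyond it; transfer numbers above 2 are rare in modern
  practice, and above 10 essentially unknown.
* A cycle whose probability underflows to zero under the current
  parameters (structurally impossible data, e.g. an observed twin with a
  viability numerically at 0) is floored at the smallest positive double
  and reported by `cycle_id`, rather than silently clamped.
* Starting values are moment-matched: the U intercept from the overall
  success rate inflated by a factor 2 (success understates receptivity
  because it also requires a viable embryo), the E intercept from the
  per-embryo implantation rate among successful cycles, slopes at zero.
  These are cheap, reproducible and robust across the simulated regime;
  the likelihood surface in that regime is well behaved, and the polished
  optimum does not depend on them.
* Standard errors (inverse observed information) are exposed only as a
  diagnostic; all inference below is by likelihood-ratio tests, which
  behave better than Wald tests in these models at realistic sample
  sizes.

AIC is $-2\log L + 2p$ and BIC is $-2\log L + p\log n$ with $n$ = the
number of **cycles**: the outcome is observed at the cycle level, so the
cycle count is the appropriate BIC sample size (the choice is immaterial
for the E-vs-U placement comparison, where parameter counts are equal).

## Testing a patient-level variable

A patient-level covariate may act through either sub-model, so testing
"is this variable associated with outcome?" involves an implicit model
choice. `eu_test_variable()` implements the strategies:
Found-in-Either (either 1-df LR test significant at $\alpha$ —
anti-conservative, roughly 8% size at a nominal 5%), Found-in-Both (both
significant — conservative, roughly half the nominal size), Bonferroni
(either test at $\alpha/2$ — close to nominal, slightly conservative),
Global (one 2-df LR test of the variable in both sub-models — close to
nominal), and the two pre-specified single tests. Ties at exactly
$\alpha/2$ have probability zero for continuous statistics, so strict
inequality is used throughout.

A correctly pre-specified single test is the most powerful option, but an
*incorrectly* pre-specified one loses more power than correct
specification gains; unless the sub-model is genuinely known in advance,
the Bonferroni strategy is the recommended default.

## Sub-model selection and evidence grading

`eu_select_submodel()` compares the E and U placements (equal parameter
counts, so AIC and BIC agree exactly) and `eu_select_models()` compares
all four inclusion models. BIC with $n$ = cycles is recommended for the
four-model choice: AIC picks the both-sub-models model for a truly
single-sub-model effect an order of magnitude more often than BIC.

The absolute IC difference between the E and U placements approximates
twice the log Bayes factor, graded by `eu_raftery_grade()`:
$[0,2)$ Weak (50–75% expected correct), $[2,6)$ Positive (75–95%),
$[6,10)$ Strong (95–99%), $\ge 10$ Very strong ($>99$%). The printed
band ends overlap in the usual presentation of this rule; this package
imposes half-open bands, assigning a boundary value to the higher grade.
Exact IC ties (probability zero, but possible with pathological data) are
recorded as ties and excluded from correct/incorrect tallies.

## The simulator: what it emulates

`eu_scenario()` / `eu_simulate()` generate data from
$$\operatorname{logit} u = \alpha_u + \beta_u U + \beta_{up} P, \qquad
  \operatorname{logit} e = \alpha_e + \beta_{ep} E_p + \beta_{ee} E_e
  + \beta_{ep2} P,$$
with $U \sim N(-0.5, 0.5^2)$, $E_p \sim N(-0.1, 0.3^2)$ (a patient-level
covariate acting in the embryo sub-model), $E_e \sim N(3, 0.6^2)$
(embryo-level), $P \sim N(0,1)$ (the putative variable under study),
$\alpha_u = 0.1$, $\alpha_e = -3.66$, unit fixed coefficients, and a
fixed 30% single / 70% double transfer mix. These defaults are calibrated
to a large UK multi-centre registry and are treated as the study
conditions, not tuning knobs: under the null they give a pregnancy rate
of about 19.7% and twin rate of 3.2% (4.6% among double transfers),
rising to about 24.8% and 6.9% with both $P$ effects at 1.

Two generator decisions were genuinely open:

* $E_e$ is drawn **independently per embryo**, matching its role as the
  embryo-level predictor; drawing it once per cycle would induce
  within-cycle viability correlation and raise the double-transfer twin
  rate above the registry-calibrated 4.6%. A `ee_per_embryo = FALSE`
  switch provides the per-cycle variant for sensitivity analyses.
* The SET/DET mix is fixed exactly at `round(prop_double * n)` double
  transfers in randomised positions rather than drawn binomially, so the
  design fraction is identical in every replicate.

What the simulator does *not* emulate: categorical covariates, repeat
cycles per couple (and any resulting correlation), donor structures,
treatment-policy selection effects, or departures from the EU
independence assumptions. Passing calibration tests therefore shows the
methods work when the EU model is true, not that real datasets satisfy
it.

## The study engine

`eu_rejection_study()`, `eu_classification_study()` and
`eu_four_model_study()` replicate dataset simulation + analysis and
report proportions with Monte-Carlo standard errors
(`eu_mc_precision()` gives the design half-width: ±0.6 points on a 5%
rate and ±1.3 points on a 50% rate at 6000 replications). Design
decisions:

* **Paired replicates.** Within a replicate, all strategies are evaluated
  on the same fitted models, removing between-strategy Monte-Carlo noise
  from comparisons (power orderings are then replicate-wise properties).
* **Seeding.** Each (scenario, replicate) derives its own seed via
  `eu_derive_seed()` (two exact Lehmer steps mod $2^{31}-1$), so results
  are independent of loop order and any single replicate can be re-run in
  isolation.
* **Failed fits.** A replicate in which any required fit fails to
  converge is dropped and counted (`n_dropped`), and proportions use the
  reduced denominator. Dropping with disclosure avoids silently biasing
  rejection rates; drop rates are below 1% in the simulated regime.
* **Null classification truth.** In a no-effect scenario the E placement
  is used as the reference "correct" label, so an unbiased selector
  scores 50%.
* **Evidence-band pooling.** The band-calibration table pools replicates
  across all single-sub-model-effect scenarios at a given sample size
  (effect sizes 0.1–1 in E or in U); which scenarios enter the pool is a
  reporting choice, and this one is documented rather than configurable.

`eu_naive_logistic_power()` is the comparator an analyst would get from
standard software: one logistic model, the pregnancy rate as event rate,
the cycle count as sample size. Its intercept is solved so the *marginal*
event rate matches exactly (Gaussian quadrature + root finding). It
over-states the power actually available for a sub-model effect, because
success in the EU mechanism additionally requires the other component.

## Problem sizes used in the packaged tests

The test suite runs the simulation studies at desk scale: 2000
replications for the type-I-error table at 400 cycles, 1000 for the
classification rates, 500 per scenario (ten scenarios) for the pooled
evidence-band calibration, parameter recovery at 100,000 cycles, and
power-curve checks at a few hundred replications. `scripts/acceptance.R`
re-runs the same experiments (6000 replications for the type-I table,
matching the original design's precision) from a single command-line
seed. Monte-Carlo standard errors accompany every proportion, and all
calibration comparisons are made at twice the Monte-Carlo precision.

## Known limitations

Single treatment per couple only; no random effects; numeric covariates
only (factor encoding is the caller's responsibility); no Wald inference;
evidence grades rest on the BIC-as-Bayes-factor approximation, whose
accuracy improves with sample size; and the four-model AIC/BIC behaviour
is characterised under the simulator's conditions, which assume the EU
model is true.
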