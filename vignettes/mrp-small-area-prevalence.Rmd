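---
title: "Small-area prevalence by MrP: model, frame, and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area prevalence by MrP: model, frame, and uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpprev)
```

## The problem

Surveillance surveys of a behaviour such as menthol cigarette use among
adults who smoke are usually powered for national estimates. Sub-national
domains (here: geographic divisions) crossed with survey wave and
demographic subgroup leave handfuls of respondents per cell, so direct
estimates are unusable. Multilevel regression and post-stratification (MrP)
borrows strength across cells in two steps:

1. **Regression.** A multilevel logistic model predicts the outcome
   probability $\hat\pi_j^{d,t}$ for each of $J = 72$ demographic cells
   (sex $\times$ age group $\times$ race/ethnicity $\times$ SES) in every
   domain $d$ and wave $t$.
2. **Post-stratification.** Cell predictions are averaged with weights
   equal to the number of people in each cell who belong to the target
   population (adults who smoke):
   $$\hat p^{d,t} = \frac{\sum_{j=1}^{72} N_j^{d,t}\,\hat\pi_j^{d,t}}
                         {\sum_{j=1}^{72} N_j^{d,t}}.$$
   Subgroup estimates restrict the sum to the relevant cells without
   refitting.

## Step 1: the multilevel model

All nine candidate specifications (`default_model_specs()`) share the fixed
structure: main effects of sex, age group, race/ethnicity and SES, the
domain-level labor-force participation rate mean-centred within domain, the
time basis, and the interactions sex:race, age:race, sex:age and
sex:age:race (so the three-way interaction is identified). They differ in:

* **time basis** — linear (`model1`), categorical wave indicators
  (`model2`), or piecewise-linear trends with hinge terms
  $\max(0, t - k)$ giving a "bend" at knot $k$ (`model3`-`model9`);
* **random intercepts** — domain in all; race-within-domain added in
  `model8`; domain plus wave in `model9`;
* **weighting** — survey weights rescaled to sample size within
  domain-wave in all but `model9`.

With the canonical 13 waves (indices 0-12) the knots sit at wave indices 6,
7 and 10. Waves, not calendar years, index time: the first wave is time 0
and spacing between waves is taken as unit. For shorter synthetic timelines
knots are scaled proportionally onto integers strictly inside the range;
when two scaled knots collide the earlier one is shifted down one wave so
the two-bend specifications stay identifiable. Total parameter counts are
27 shared fixed-effect columns + time columns + one variance component per
random intercept, giving 29, 40, 30, 30, 30, 31, 31, 32, 32 for the nine
candidates.

**Estimation.** Fitting is delegated to `lme4::glmer` with the rescaled
weights treated as frequency weights. The package default is `nAGQ = 0`,
which profiles the fixed effects inside the penalized IRLS step and leaves
only the variance parameters to the outer optimizer. The full Laplace
criterion (`nAGQ = 1`) optimizes all 29-40 parameters by derivative-free
search; on a 9,600-row synthetic survey that took over a minute per model
and frequently tripped lme4's convergence checks, while `nAGQ = 0` finishes
in under a second with near-identical predictions. `nAGQ = 0` is also the
closer analogue of the pseudo-likelihood fits historically used for
weighted multilevel surveillance models. The choice is exposed as an
argument. Convergence tolerance and iteration caps are lme4's, with the
bobyqa optimizer and an evaluation budget of $10^5$; optimizer failure is
reported via `converged = FALSE` rather than an error, and non-converged
fits are excluded from AIC/BIC selection (smallest AIC, ties by BIC then
parameter count).

**Prediction.** Cell predictions use the fixed effects plus posterior-mode
(empirical Bayes) random intercepts for observed groups; groups never seen
in the data contribute zero, the prior mode.

## The post-stratification frame

$N_j^{d,t}$ counts adults who smoke, estimated from a large reference
survey (BRFSS-like) and cell population totals (census-like):

1. **Direct estimates** $p_{id}$: weighted smoking prevalence per cell with
   the Kish effective-sample-size binomial variance
   $v_{id} = p(1-p) / n_\text{eff}$, $n_\text{eff} = (\sum w)^2/\sum w^2$.
   The synthetic design has no strata or clusters, so a design-based Taylor
   variance would add nothing; the contract that variance shrinks with
   effective information is preserved.
2. **Model estimates** $p_{im}$: per wave, a weighted logistic regression
   of smoking on domain, sex, age, race and SES with the four interactions
   domain:race, sex:age, sex:race and age:race, with delta-method variance.
3. **Composite.** $\theta_i = a_i p_{id} + (1-a_i) p_{im}$ with
   $a_i = v_{im}/(v_{im}+v_{id})$: the direct estimate gets more weight
   when the model estimate is relatively unstable.
4. **Fallback.** The model estimate is used outright when the direct one is
   unusable: cell $n < 5$, $p_{id} \in \{0, 1\}$, or implied smoker count
   $n \cdot p_{id} < 1$. Cells with degenerate variance are routed here
   before compositing.
5. **Totals and raking.** $N^{raw}_j$ = chosen prevalence $\times$ cell
   population, then iterative proportional fitting within each domain-wave
   so that single-factor margins match reference-survey smoker totals.

**A note on margins.** The reference margins are "number of people of level
$\ell$ who smoke" per domain-wave. Synthetic weights have unit mean, so
weighted counts live on the sample scale; margins are therefore computed as
weighted smoking prevalence within the level times the population of the
level. The four factors' raw margin vectors then have slightly different
grand totals (each is a different slice of the same noisy survey), and IPF
only converges when all factors share one total — so each factor's margins
are rescaled to the common domain-wave total (overall prevalence times
total population). IPF sweeps factors in the fixed order sex, age, race,
SES, to relative tolerance $10^{-8}$, at most 1,000 sweeps; order and
tolerance are declared defaults, chosen for determinism.

## Confidence intervals

Nonparametric bootstrap: respondents of the outcome survey are resampled
with equal probability and with replacement within each domain-wave
stratum, keeping stratum sizes fixed; the selected model is refit on each
replicate and post-stratified against the *fixed* frame (only the outcome
survey is resampled — the frame comes from independent, much larger
sources). Intervals are percentile, type-7 (linear interpolation) quantiles
at $\alpha/2$ and $1-\alpha/2$; the default is 1,000 replicates at 95%.
Replicates keep their original rescaled weights. Non-converged replicates
are dropped and logged; more than 10% dropped is a hard failure.

## Validation

Agreement between modeled and gold-standard direct estimates is summarized
by the concordance correlation coefficient, computed with population
(1/n) moments:
$$\rho_c = \frac{2\,\mathrm{cov}(x,y)}
                {\mathrm{var}(x)+\mathrm{var}(y)+(\bar x-\bar y)^2},$$
which factors into precision (Pearson $r$) and accuracy ($\rho_c / r$).
With exactly two raters the overall CCC reduces to Lin's coefficient, so a
single implementation serves both names. Pairing is joint across all
domain-waves within each subgroup family; groups with fewer than three
pairs are skipped with a warning. No interval is attached to the
coefficient (point values only).

## The synthetic world

The generator (`truth_config()`, `simulate_study()`) emits four artifacts
with known truth: a cell population table, a small multi-wave outcome
survey, a large smoking-status survey, and an independent gold survey that
reports direct estimates with binomial variances rather than microdata.
Its defaults describe one fixed world:

* 72 cells per domain-wave; cell populations uniform on [2,000, 50,000];
* outcome model: baseline (male, 50+, reference race, high SES) prevalence
  28%, strong positive effect for the high-prevalence race group (+2.2
  log-odds), moderate effects elsewhere, a rising linear trend of 0.06
  log-odds per wave, domain intercept SD 0.3, and two small interactions —
  chosen to mirror the qualitative structure of US menthol surveillance
  (baseline around a quarter to a third, one group above 80%, slow rise);
* smoking model: 20% baseline, higher at lower SES;
* weights lognormal with sdlog 0.5, normalized to unit mean per
  domain-wave — they exercise the weighted-likelihood path without claiming
  to reproduce any real design's weight distribution;
* respondents drawn per domain-wave with cell membership proportional to
  cell population (gold survey: proportional to true smoker counts).

What a green test does **not** establish: the generator has no panel
attrition, no recruitment-mode changes, no frame changes mid-series, no
measurement differences between surveys, and its weights are noninformative
(independent of the outcome). Real-data deployments face all of these; the
synthetic study verifies the estimator machinery, not robustness to design
features it does not emulate.

## Numerical choices and degenerate inputs

* Reference levels: male, age 50+, reference race, high SES, wave 0 —
  arbitrary but fixed; predictions are invariant.
* "Not reported" education or income is folded into the lower binary level
  before the SES composite (high = both high, low = both low, else
  moderate).
* Zero-population subgroups post-stratify to an explicit `no_support`
  marker, never silently to 0.
* Both composite variances zero is an error (undefined blend); a single
  zero variance gives the stable source full weight.
* A single-domain dataset and rank-deficient designs raise immediately
  with the offending columns named.
* All generators derive independent RNG substreams from one seed and
  restore the caller's RNG state; identical configurations are
  byte-identical at the CSV level.

## Known limitations

* Estimation accuracy versus the original SAS pseudo-likelihood software is
  not asserted anywhere — only oracle equivalence (zero-variance fits match
  weighted IRLS to $10^{-4}$) and truth recovery on synthetic data.
* The race-within-domain and wave random intercepts use a single shared
  variance each ("variance components" structure); no crossed slopes.
* The bootstrap refits the full model per replicate but holds the frame
  fixed; frame uncertainty is not propagated.
* Raking is joint over the four factors within domain-wave; a sequential
  per-factor alternative reading exists and would give slightly different
  (still margin-matching) totals.
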