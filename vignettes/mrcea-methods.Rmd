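---
title: "Methods: genetically instrumented health-economic effects and intervention cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetically instrumented health-economic effects and intervention cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcea)
```

`mrcea` estimates the causal effect of a binary disease exposure (a
site-specific cancer) on two health-economic outcomes — annual health care
cost in GBP and annual QALYs — using a polygenic risk score as a genetic
instrument, and feeds those estimates into a Monte-Carlo cost-effectiveness
simulation of a population-wide preventative intervention. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the package's validation on synthetic cohorts does and does not show
about real data.

## The identification problem

Conventional regressions of costs or QALYs on disease status are
confounded: behaviours, comorbidity and socioeconomic position influence
both. Germline genetic variants associated with disease liability are fixed
at conception, so a score built from them can serve as an instrumental
variable provided three assumptions hold: *relevance* (the score predicts
the disease; testable, summarised here by the first-stage robust F and the
McFadden pseudo-R² of a logistic fit of disease on the score),
*independence* (the score shares no confounders with the outcome; made
plausible by adjusting for genetic principal components, and untestable),
and the *exclusion restriction* (the score affects the outcome only through
the disease; probed here by per-variant heterogeneity diagnostics and
negative controls).

## Estimators

**2SLS.** `fit_2sls()` computes the just-identified IV estimator in closed
form, `β̂ = (Z'X)⁻¹Z'y` with instrument matrix `Z = [1, z, C]` and design
`X = [1, D, C]`. This is algebraically the two-stage procedure (regress
exposure on instrument and covariates; regress outcome on the fitted
exposure and covariates), and with no covariates it reduces exactly to the
Wald ratio `cov(y, z)/cov(D, z)` — a property the test suite asserts to
1e-10 relative error. The variance is the IV sandwich
`(Z'X)⁻¹ Z'diag(e²)Z (X'Z)⁻¹ · n/(n−k)` with residuals `e` formed from the
*observed* exposure, i.e. an HC1-style robust estimator. HC1 was chosen as
the common econometric default among robust flavours; no correction beyond
the sandwich is applied for the generated-regressor aspect of the first
stage, and this is the package's documented convention. The binary exposure
enters untransformed, so the estimand is the additive structural mean — the
population-average change in the outcome caused by having versus not having
the disease, under a constant-effect assumption.

**Covariates.** `mr_covariates()` builds age, a male indicator, the genetic
principal components present in the cohort, and recruitment-centre
indicators (first level dropped). The synthetic default is 10 principal
components; the number is configurable and real analyses commonly use 40.

**QALY scaling.** QALY fractions are multiplied by 100 before fitting
(`scale_qaly()`), so QALY effects read as percentage points of a QALY per
year of follow-up; they are annual, not cumulative.

**OLS comparison and the Hausman test.** `fit_ols()` is the conventional
multivariable regression with HC1 standard errors. `hausman_test()` refers
`(β_iv − β_ols)²/(se_iv² − se_ols²)` to χ²(1). The contrast-variance
estimator in the denominator is not guaranteed positive in finite samples;
when it is non-positive the statistic is clamped to 0 with p = 1 and a
warning. This makes the test conservative in exactly the samples where the
IV estimate is too precise for the contrast to be estimated, which we judge
preferable to reporting a negative variance. The test's power is low when
the instrument is modest, since `se_iv` dominates the denominator.

**Missing costs.** Primary-care cost components are commonly missing by
linkage (centre), so the generator makes cost missingness depend on centre
only — missing at random given covariates. `impute_and_pool()` implements a
deliberately simple imputation: a linear regression of observed costs on
the covariates plus the exposure, with missing values replaced by the
prediction plus a residual resampled with replacement, repeated `m` times
and pooled by Rubin's rules (`pooled variance = W + (1 + 1/m)B`). This is
not full chained-equations imputation; it is sufficient for the package's
purpose of propagating missing-data uncertainty into the pooled standard
error, and the tests verify the pooled estimate tracks the complete-data
estimate under the generator's MAR mechanism.

## Sensitivity analyses

`stratified_mr()` refits within sex, age-band, or arbitrary custom strata
(sex is dropped from the covariates inside sex strata; centre indicators
are rebuilt per stratum; strata without both exposure classes are reported
as skipped). `negative_control()` regresses the outcomes on the score of a
sex-specific cancer within the sex that cannot express it — an estimate
distinguishable from zero would indicate the score reaches the outcomes
other than through the cancer. `per_snp_estimates()` fits
exposure-on-dosage and outcome-on-dosage regressions per variant, forms
Wald ratios with first-order delta-method standard errors
`se_outcome/|β_exposure|` (ignoring the exposure-side uncertainty, the
standard two-sample convention), and `ivw_pool()` combines them by
fixed-effect inverse-variance weighting with Cochran's Q on
`n_snps − 1` degrees of freedom. Variants whose exposure association is
below 1e-12 in absolute value are excluded with a warning rather than
producing unstable ratios. An MR-Egger intercept regression
(`egger_regression()`) is available as an optional diagnostic; it is not
part of the package's headline checks because pleiotropy-robust estimator
choice is configuration, not fixed behaviour.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the estimators
assume, with known truth:

* **Genotypes.** Independent biallelic variants, dosages Binomial(2, af).
  Linkage disequilibrium is deliberately not modelled; the instruments are
  exchangeable and uncorrelated by construction.
* **Liability.** `L_i = Σ_j g_ij β_j + c_L U_i + logistic noise`, with
  `U_i ~ N(0,1)` a latent confounder. Logistic noise makes the per-variant
  `β_j` genuine log-odds ratios, matching GWAS effect-size semantics.
  Disease status is `L` above the *empirical within-sample* quantile at
  `1 − prevalence` (among the eligible sex for sex-specific cancers): the
  empirical threshold guarantees realised prevalence near target even in
  small test cohorts, where an analytic threshold would drift. The weight
  table reports noisy estimates of the true `β_j` (SEs drawn in
  0.02–0.05), emulating a two-sample design where the GWAS and the outcome
  cohort are disjoint.
* **Costs.** `cost = baseline(age, sex) + β_cost·D + c_cost·U + noise`,
  truncated at zero. The noise is lognormal — emulating the strong right
  skew of annual claims data (median well below the mean, long upper tail)
  — anchored at its *median* (offset £400): a median-anchored lognormal has
  median-zero noise bounded below by −£400, so the truncation at zero
  almost never binds (<1% at the defaults) and the additive structural
  model stays exact up to a constant shift. A mean-centred lognormal at
  realistic scales would instead push roughly a tenth of costs negative
  and the truncation would distort the very estimand the generator is
  supposed to pin down. Defaults (baseline £650, noise SD £1,200) give a
  median annual cost near £650 with an interquartile range of roughly
  £440–£1,100, in the region reported for UK cohort costing studies.
* **QALYs.** `q = baseline_q − |β_qaly|·D + c_q·U + Gaussian noise`,
  clamped to [0, 1], with a small age gradient; baseline 0.78 matches the
  typical predicted annual QALY of middle-aged UK cohort participants.
  Cost and QALY noise are independent given disease and the confounder;
  the joint distribution of the two outcomes is not otherwise specified by
  the sources the package models, and this is the simplest coherent
  choice.
* **Missingness.** Per-centre missingness probabilities proportional to
  the centre index, averaging to `missing_rate` — missing at random given
  covariates, driven by a single administrative variable.
* **Pleiotropy.** `inject_pleiotropy()` adds a direct per-allele cost
  effect for chosen variants, violating the exclusion restriction in a
  controlled way; the injection is recorded in the truth record.

Generation is bit-reproducible under a fixed seed (the RNG kind is pinned)
and restores the caller's RNG state.

What passing tests on these cohorts shows: the estimators are correctly
implemented (algebraic identities, parameter recovery, nominal test size
and CI coverage, null negative controls, Q sensitivity to injected
pleiotropy). What it does not show: robustness to linkage disequilibrium,
assortative mating, population stratification beyond what principal
components capture, age-dependent incidence, survival/censoring processes,
or real cost-coding idiosyncrasies — none of which the generator emulates.

## The intervention simulation

`run_intervention_sim()` propagates three uncertain quantities through
`n_draws` Monte-Carlo draws:

1. the baseline case proportion `p = n/N` with binomial standard error
   `sqrt(p(1−p)/N)` (`proportion_se()`; the square root is part of the
   definition — the un-rooted variance form occasionally quoted for this
   quantity yields absurd magnitudes and is not used), drawn normal,
   truncated to (0, 1) by redraw, and rescaled to counts;
2. the intervention odds ratio, drawn on the **log scale** by default with
   the SE recovered from the 95% CI width (`(log U − log L)/3.92`). Log-
   scale drawing keeps every draw positive, which a normal draw of a ratio
   does not guarantee; natural-scale drawing is available via
   `or_scale = "natural"` for fidelity to descriptions that do not specify
   the scale;
3. the cost effect (GBP/year) and QALY effect (percentage points/year) of
   the disease, drawn normal with SEs from their CI widths,
   **independently** — no correlation between them is specified by the
   estimates they summarise, and none is imposed.

Per draw, the risk difference `RD = nOR/(N − n + nOR) − n/N` (negative for
a protective OR) converts the odds ratio to an absolute risk change at the
drawn prevalence;
`ΔCost = drug_cost + RD × cost_effect`,
`ΔQALY = RD × qaly_effect` (positive when preventing a harmful disease),
and `NMB = λ·ΔQALY/100 − ΔCost`. Medians and 2.5/97.5 percentiles
summarise the draws; neither costs nor QALYs are discounted, consistent
with effects expressed per average year of follow-up. The "all" scenario
uses overall counts rather than aggregating age-band runs. The break-even
price is `drug_cost + median(NMB)` — NMB draws translate one-for-one with
price — and the implementation verifies it by re-running the simulation at
that price with the same seed (median NMB returns ~0 exactly).

Because the draws of `RD` and the cost effect multiply, the median of the
product is not the product of the medians: with a protective OR drawn on
the log scale the simulated medians sit a little off the deterministic
point-estimate arithmetic (for the prostate scenario, point arithmetic
gives ΔCost ≈ £466.4 and NMB ≈ −£450.3, while published stochastic medians
for the same inputs are a little lower in magnitude on cost and NMB). The
package reports its own simulated medians and documents the deterministic
oracle alongside; it does not force agreement, since the exact draw scheme
behind any particular published median is not recoverable from summary
descriptions.

## Numerical and design choices

* PRS weighting: the default `"beta"` scheme is the standard weighted
  allele count, which makes the 2SLS fit the usual PRS-based MR estimator;
  the `"precision"` scheme (`β_j/se_j²`) is available because weight tables
  are sometimes described as precision-weighted. 2SLS point estimates are
  invariant to instrument scaling (asserted to 1e-9 relative), so the
  choice affects diagnostics' units, not estimates. Scores are left
  unstandardised for the same reason.
* Harmonisation assumes the weight table and dosage columns refer to the
  same strand; an effect/other allele swap flips dosages (`d → 2 − d`,
  shifting every score by a constant and leaving regressions unchanged),
  while strand-ambiguous A/T and C/G variants are accepted unchanged and
  flagged.
* Logistic fits for the pseudo-R² use IRLS with tolerance 1e-8 and at most
  100 iterations; non-convergence and complete separation raise explicit
  errors rather than returning a misleading value.
* Rank-deficient designs and zero-variance instruments raise errors; no
  estimator returns NaN.
* 95% intervals use the conventional 1.96 multiplier throughout, matching
  the CI-to-SE back-conversion in the simulation inputs.
* The pipeline derives per-stage seeds from one global seed by fixed named
  offsets, so stages rerun in isolation reproduce their in-pipeline
  output; all tabular output is delimiter-explicit UTF-8 with C-locale
  numbers (GBP amounts never acquire thousands separators), and header
  comments carry the package version, seed and a config hash.

## Validation problem sizes

The package's validation experiments (in `tests/testthat/`) use: 200
replicate cohorts of n = 20,000 for parameter recovery (true cost effect
£800/year, QALY effect −5 percentage points/year; means recovered within
two Monte-Carlo standard errors, 95% CI coverage within [0.91, 0.99]); 500
replicates of n = 5,000 for the Hausman test's size under an unconfounded
generator; 100 replicates of n = 4,000 each for negative-control nullity
and IVW–2SLS agreement; and 200 replicates of n = 2,000 for the Cochran's-Q
pleiotropy comparison. The recovery experiment raises the cost baseline to
£1,500 and tightens QALY noise to 0.05 so that boundary truncation at £0
and clamping at QALY 1 (kept below 0.1% of individuals) cannot contaminate
the linear-estimator check; this is an experiment-design choice, made so
the check isolates estimator correctness from boundary censoring, while
the generator's defaults stay at the realistic values described above.

## Known limitations

Weak-instrument-robust inference (Anderson–Rubin), LATE decompositions,
correlated-instrument IVW, weighted-median/mode and outlier-removal
pleiotropy estimators, survival modelling of follow-up, discounting and
lifetime extrapolation are all out of scope. The Hausman clamp makes that
test conservative. The imputation model is a single linear regression, not
chained equations. The generator's independence assumptions (variants,
outcome noises) are simplifications a real cohort will violate to some
degree; conclusions about estimator behaviour on real data should lean on
the diagnostics the package reports (F, pseudo-R², Q, negative controls)
rather than on the synthetic validation alone.
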