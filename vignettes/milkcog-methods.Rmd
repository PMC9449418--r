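---
title: "Methods: joint nutrient-outcome association under collinearity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint nutrient-outcome association under collinearity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkcog)
```

## The statistical problem

A 14-nutrient human-milk panel — fatty acids (TSFA, TMUFA, TPUFA in g/100ml,
ARA and DHA in mg/100ml, the ratios ARA/DHA and n-6/n-3), phospholipids (PC,
PE, PI, SPH in mg/100ml) and choline metabolites (free choline, PCho, GPC in
µmol/l) — is to be related to infant cognition (MSEL subscale T-scores and
their composite) and temperament (three IBQ-R factors) in a cohort of a few
dozen infants under six months, controlling age at visit, sex, collection
site and a household-income indicator. Nutrients within a biochemical family
are strongly correlated, so the package treats the panel as a correlated
system rather than 14 independent exposures.

Three models organise the analysis:

* **M0 (marginal):** `Y ~ 1 + age + sex + site + income + X_j`, one nutrient
  at a time.
* **M1 (joint):** `Y ~ 1 + age + sex + site + income + X_{j1} + ... + X_{jq}`
  with at most one nutrient per correlation cluster.
* **M2 (baseline):** `Y ~ 1 + age + sex + site + income`, the reduced model
  for the nested F-test.

## Standardization conventions

Nutrient concentrations are z-scored within the analysis subset at hand; the
MSEL and IBQ-R models are fit on different subject subsets, so
standardization statistics are computed per subset rather than on their
union. Outcomes are z-scored inside the fitting routines. Confounders stay on
their raw scale. The reported "standardized coefficient" is therefore the OLS
coefficient of a z-scored nutrient on a z-scored outcome adjusted for raw
confounders — the convention under which a coefficient of 0.54 with raw
p = 0.0006 at 36 residual degrees of freedom reconstructs a 95% CI of
[0.25, 0.83], matching the arithmetic of the printed marginal results.
Missing household income (an indicator) is mean-imputed from the observed
values; fractional imputed values are intentional.

## Clustering and the Dunn index

Pairwise Pearson correlations are computed on raw concentrations (the result
is scale-invariant, asserted in tests). The clustering distance is the
**signed** `1 - r`: the thresholding logic operates on raw correlation
coefficients and all the structure of interest is positive; `1 - |r|` is
available behind the `absolute` flag for panels where strong negative
correlations should also bind.

A threshold partition at `Tc` is defined as the connected components of the
graph whose edges join pairs with `r >= Tc`. The inclusive rule (rather than
strict `>`) is deliberate: it makes the graph construction agree exactly with
cutting the single-linkage merge tree at height `1 - Tc` (merges happen at
distance *equal to* the cut height), and it is the convention under which
stability intervals are naturally reported as `tc_low < Tc <= tc_high`. The
two constructions, plus a third via deleting minimum-spanning-tree edges
below the threshold, are verified to agree on hundreds of random instances.

The number of clusters maximizes the Dunn index: minimum single-linkage
separation between clusters divided by maximum within-cluster diameter.
Singleton clusters contribute diameter zero — the alternative (excluding
them) cannot reorder partitions whose maximum diameter comes from a
multi-member cluster, but the choice is stated here because an all-singleton
partition makes the index undefined (signalled as a distinct error, as is the
one-cluster partition). Ties in the Dunn index are broken toward fewer
clusters, then toward the lower threshold: parsimony first, determinism
always.

**A known instability.** The Dunn criterion on single-linkage cuts is a ratio
of two order statistics of the correlation matrix, and at n ≈ 50 the sampling
noise of individual correlations (standard error ≈ 0.1) routinely lets a
near-singleton partition win: two nutrient pairs whose empirical merge
heights happen to be almost equal produce a large separation-to-diameter
ratio. The package's default correlation target has a population optimum of
k = 7, but cohorts of the study's size frequently select finer partitions. A
finer partition weakens the one-per-cluster constraint (the selection search
simply gains candidates), so downstream selection degrades gracefully; the
behaviour is surfaced rather than patched because it is a property of the
published procedure itself.

## Cluster-constrained best subset

Candidates are all nutrient subsets with at most one member per cluster,
including the empty set; for cluster sizes {4, 1, 2, 4, 1, 1, 1} that is
5·2·3·5·2·2·2 = 1200 candidates. Each candidate is fit by OLS with the four
confounders always included, and scored by adjusted R² with the regressor
count equal to selected nutrients + 4 confounders (excluding the intercept) —
the convention that reproduces all five published (R², adjusted R²) pairs
exactly. Rank-deficient candidates are skipped with a count, never crash the
search. Ties in adjusted R² are broken toward fewer nutrients, then
lexicographic order.

Overall significance is `F = ((RSS_M2 - RSS_M1)/q) / (RSS_M1/(n - k - 1))`
against the F distribution. Because the nutrient set was chosen to maximize
fit, this p-value is **anti-conservative**; the fit object carries that label
and the output log repeats it. The FDR family for these model p-values is the
instrument's outcomes (six MSEL models, three IBQ-R models, as two families),
configurable because the printed adjusted values cannot be uniquely
reverse-engineered from a single family definition; the marginal scan's
default family is likewise the full nutrient-by-outcome grid of one
instrument, with a per-outcome option. AIC is reported per fit but is never
the selection objective.

## Cross-validation and follow-up prediction

Cross-validation keeps the selected nutrient set fixed and refits
coefficients per training fold: this evaluates the *selected model*, not the
selection procedure, and the optimism that entails is recorded in the result
metadata. Folds are uniform random without stratification (no stratification
rule is implied by the design). Per repetition, out-of-fold predictions are
pooled across the five folds into a single Pearson correlation and mean
squared error — pooling (rather than averaging per-fold correlations) is what
makes the significance threshold at the full n meaningful, e.g. r* ≈ 0.32 at
n = 38 and α = 0.05. One hundred repetitions are the default.

Follow-up prediction applies the frozen coefficients to each subject's
baseline nutrients (standardized with the training means/SDs) and baseline
confounders. The age covariate defaults to the baseline age, because the
coefficients were trained on baseline ages and re-using follow-up ages would
extrapolate the age term far outside its training range; `use_followup_age =
TRUE` exposes the alternative since the original procedure is not specified
on this point. Follow-up visits are binned as (6,9], (9,12] and (12,18]
months (lower bound exclusive: a 7.63-month visit belongs to the first bin);
per bin, the Pearson correlation between predicted and observed scores is
tested with `t = r√((n−2)/(1−r²))` on n − 2 df. Bins with fewer observations
than `min_bin_n` (default 10 in the pipeline) are skipped, mirroring the
exclusion of under-sampled follow-up windows; `followup_predict()` itself
errors below 3.

## The synthetic cohort generator

The generator exists so that every stage is testable without the original
cohort. It emulates:

* **Nutrient marginals** — the published mean/SD of each of the 14 nutrients.
  Sampling is multivariate normal on the standardized scale, affinely mapped
  to (mean, sd) and clamped at zero. The clamped fraction is attached to the
  result; for right-skewed nutrients whose published mean is less than about
  2.33 SDs above zero (DHA at 8.35/5.14, free choline at 216/140) it
  necessarily exceeds 1% under normality — a limitation of the normal
  marginal, documented rather than hidden. Real milk concentrations are
  right-skewed; the generator does not emulate skewness, assay error, or
  lactation-stage kinetics.
* **Correlation structure** — a block target constructed once to reproduce
  the published single-linkage structure: a fatty-acid chain holding
  TSFA–TMUFA–TPUFA–ARA together up to thresholds near 0.77, the DHA–ARA/DHA
  pair, a phospholipid block losing PI above 0.69 and PC above 0.74, PCho
  joining choline at 0.50, GPC joining the phospholipids at 0.53 (making
  0.53 the lower edge of the optimal stability interval), and TSFA–PC = 0.28
  as the strongest cross-family link. The hand-specified blocks are repaired
  to the nearest positive semi-definite matrix by eigenvalue clipping
  (Frobenius distance ≈ 0.034; repairs beyond 0.05 are rejected as
  mis-specification). The published Dunn values themselves are **not**
  matched — they depend on the full unpublished matrix.
* **Outcome models** — the published coefficient rows for gross motor,
  receptive language, surgency and regulation, with residual noise calibrated
  so the model explains the published R² (`target_r2`): with the outcome
  z-scored, R² equals the variance of the linear predictor, so the residual
  SD is derived from the realized linear-predictor variance as
  `sd(lp)·√((1−R²)/R²)`. Outcomes with no published model are
  confounder-free noise. MSEL subscales are mapped to the T-score scale
  (mean 50, SD 10). IBQ-R subscales are generated as
  `4 + 0.8·factor + N(0, 0.5)` so that the factor scoring (weighted average)
  approximately reconstructs the latent factor; the independent subscale
  noise attenuates recovered factor effects by roughly 2%, which matters for
  none of the package's checks but is stated here.
* **Design counts** — 54 subjects, 38 with MSEL, 42 with IBQ-R, 26 with both
  (assigned by stratified random draw, since only the counts are known), two
  missing income values injected completely at random, visit ages
  4.43 ± 0.83 months clamped to (0.5, 6], and follow-up visits of 27/34/25
  MSEL and 27 IBQ-R subjects with bin-appropriate ages.

Everything is reproducible from the config seed, and the written cohort CSV
uses the published column labels (`n-6/n-3`, `ARA/DHA`) with a plain-text
sidecar recording the generation parameters.

The bundled IBQ-R factor loadings are **synthetic placeholders** (the
instrument's published loading table is not redistributable): 14 subscales
assigned 6/4/4 to surgency, negative affectivity and regulation with
plausible positive weights. Users analysing real data supply their own
loading table; factors are weighted averages (`normalize = TRUE`) because the
composite is described as an average, with a weighted-sum switch.

## What passing tests do and do not show

The test suite (about 1400 assertions) verifies the machinery against
independent oracles: threshold partitions against BFS components, tree cuts
and MST edge deletion on 200+ random instances; the Dunn argmax against
exhaustive cut enumeration; the constrained best subset against exhaustive
`lm()` re-enumeration; BH against the step-up definition and
`stats::p.adjust`; the nested F against `stats::anova` and a 5000-simulation
type-I error check; marginal CI coverage at n = 42; planted-model recovery
(the published surgency coefficients at n = 200 are re-selected in ≈ 90% of
cohorts, with refit coefficients matching a large-sample oracle on the
standardized-outcome scale); and exact/null cross-validation behaviour.
Problem sizes were chosen to make Monte-Carlo error small relative to each
tolerance (2000–5000 simulations for calibration rates, n = 20000 for
distributional convergence, n = 50000–100000 for oracle refits) while keeping
the default suite to well under an hour.

Passing on synthetic cohorts shows the *procedure* is implemented correctly
and behaves as designed under the generator's assumptions — Gaussian copula,
linear effects, homoscedastic noise, missingness completely at random. It
does not validate those assumptions for real milk-nutrient data, where
skewness, nonlinear age effects and informative missingness are all
plausible.

## Known limitations

* The Dunn/single-linkage partition is unstable at study-sized n (see above).
* The joint-model F-test is post-selection; its FDR-adjusted p-values inherit
  the optimism. Cross-validation is the honest complement, and even it fixes
  the selected set.
* Single mean imputation of income understates uncertainty; with two missing
  values out of 54 the effect is negligible, and no multiple imputation is
  offered.
* The normal marginals clamp a non-trivial fraction of DHA and free-choline
  draws at zero (≈ 5% at the published mean/SD ratios).
* No penalized-regression alternatives, interaction terms, or
  selection-aware inference corrections are provided; the scope is the
  published procedure, faithfully.
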