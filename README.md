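# milkcog

Joint association analysis of human-milk nutrients with infant cognition and
temperament.

## The problem

Human milk delivers fatty acids, phospholipids and choline metabolites whose
concentrations are strongly inter-correlated. Relating a 14-nutrient panel
(TSFA, TMUFA, TPUFA, n-6/n-3, ARA, DHA, ARA/DHA, PC, PE, PI, SPH, free
choline, PCho, GPC) to infant outcomes — the five Mullen Scales of Early
Learning (MSEL) subscale T-scores and the three IBQ-R temperament factors
(surgency, negative affectivity, orienting/regulation) — therefore faces two
obstacles at cohort sizes of a few dozen: multiple testing across the
nutrient-by-outcome grid, and severe collinearity that makes an unconstrained
multiple regression uninterpretable.

`milkcog` implements a pipeline for this setting:

1. **Marginal scan (model M0).** For each nutrient *X<sub>j</sub>* and each
   outcome *Y*: `Y ~ 1 + age + sex + site + income + X_j` by OLS with *Y* and
   *X<sub>j</sub>* z-scored, reporting the standardized coefficient *r* with
   its 95% CI on *n* − 6 residual df and Benjamini–Hochberg FDR-adjusted
   p-values across the grid.
2. **Nutrient clustering.** Single-linkage clustering of the nutrients under
   distance 1 − *r* (pairwise Pearson correlation). A threshold *T<sub>c</sub>*
   cuts the merge tree into the connected components of the graph with edges
   {*r<sub>ij</sub>* ≥ *T<sub>c</sub>*}; the number of clusters is chosen by
   maximizing the Dunn index (minimum between-cluster separation over maximum
   within-cluster diameter), and the minimum spanning tree summarizes the
   correlation network.
3. **Cluster-constrained best subset (model M1).** Exhaustive search over all
   nutrient subsets with at most one member per cluster (confounders always
   included), scored by adjusted R²
   `1 − (1 − R²)(n − 1)/(n − k − 1)` with *k* = selected nutrients + 4
   confounders. Overall significance is the nested ANOVA F-test against the
   confounder-only baseline (model M2), FDR-adjusted across the instrument's
   outcomes; being post-selection, this p-value is labelled anti-conservative.
4. **Validation.** 100 repetitions of 5-fold cross-validation (selection fixed,
   coefficients refit per fold, out-of-fold predictions pooled into one
   Pearson correlation per repetition), and prediction of follow-up scores at
   6–9, 9–12 and 12–18 months from the frozen baseline model, tested with the
   Pearson t-test `t = r√((n−2)/(1−r²))`.

Because the underlying cohort data are not public, the package ships a
**synthetic cohort generator** reproducing the study's design: published
nutrient means/SDs, a block correlation target whose single-linkage structure
matches the published 7-cluster solution (stable for 0.53 < *T<sub>c</sub>* ≤
0.69), planted outcome models from the published coefficient tables, the
54/38/42/26 instrument-availability pattern, two missing income values, and
binned follow-up visits. Every stage is testable end to end against it.

## Worked example

```r
library(milkcog)

cohort <- simulate_cohort(cohort_config(seed = 42))   # study-sized cohort
frame  <- build_analysis_frame(cohort$baseline, "ibq") # 42 IBQ-R subjects

# marginal scan: 14 nutrients x 3 temperament factors
scan <- marginal_scan(frame)
head(dplyr::arrange(scan, p_raw), 3)
#>   nutrient outcome std_coef    se ci_low ci_high    p_raw     n df_resid  p_adj
#> 1 ARA      ibq_sur    0.538 0.145  0.244   0.832 0.000695    42       36 0.0292
#> 2 ARA      ibq_reg    0.480 0.142  0.193   0.768 0.00173     42       36 0.0363
#> 3 TPUFA    ibq_reg    0.467 0.160  0.143   0.791 0.00592     42       36 0.0829

# correlation clustering with Dunn-index choice of k
part <- optimal_partition(pairwise_correlations(cohort$baseline))
part
#> <milk_partition> selected k = 13 (Dunn 1.029, stable for 0.83 < Tc <= 0.84)
#>   group 1 : TSFA, TMUFA
#>   ...

# cluster-constrained best subset for surgency
fit <- best_subset_fit(frame, "ibq_sur", part$selected)
fit
#> <milk_fit> ibq_sur ~ confounders + TMUFA + ARA + DHA + PC + PE + SPH + Choline + PCho + GPC
#>   R2 0.611  adj R2 0.430  F 4.81 (p 0.000621, post-selection)  n 42

# repeated 5-fold cross-validation of the selected model
repeated_cv(frame, "ibq_sur", fit$selected, seed = 1)
#> <milk_cv> ibq_sur : 100 reps of 5-fold CV, n = 42
#>   mean r 0.441 [0.319, 0.559], significant in 99% of reps (r* = 0.304)
```

The marginal scan recovers the planted ARA–surgency signal (standardized
coefficient 0.54, raw p 0.0007, CI [0.24, 0.83], FDR-adjusted p 0.029), and
the selected joint model cross-validates with a mean out-of-fold correlation
of 0.44 against a significance threshold of 0.30. Note that at n = 54 the
empirical correlation matrix here supports a finer partition (k = 13) than
the population structure it was drawn from (k = 7): the Dunn criterion on
single-linkage cuts is sensitive to sampling noise in the correlations, which
is discussed in the methods vignette.

`run_pipeline(pipeline_config(...))` chains all stages and, given an
`output_dir`, writes each stage as CSV (participant characteristics, nutrient
summaries, marginal tables, partition table, joint-model tables, CV and
follow-up results) plus a run log.

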