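Package: milkcog
Title: Joint Association of Human Milk Nutrients with Infant Cognition and
    Temperament
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for relating a panel of 14 human-milk nutrients
    (fatty acids, phospholipids, choline metabolites) to infant cognition
    (Mullen Scales of Early Learning) and temperament (IBQ-R factors) in the
    presence of strong nutrient collinearity. Implements confounder-adjusted
    marginal association scans with standardized coefficients and
    Benjamini-Hochberg false discovery rate control, correlation-based
    single-linkage clustering with Dunn-index selection of the number of
    clusters, minimum spanning tree summaries, cluster-constrained best-subset
    regression maximizing adjusted R-squared with nested ANOVA F-tests against
    a confounder-only baseline, repeated 5-fold cross-validation of the
    selected models, and prediction of follow-up scores binned by age. A
    synthetic cohort generator reproducing the study design (nutrient
    marginals, block correlation structure, planted outcome models, follow-up
    visits) makes every stage testable without access to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
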