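# Cluster-constrained best-subset regression and nested F-tests.

test_that("candidate enumeration follows the product formula and the constraint", {
  # the published 7-group sizes {4,1,2,4,1,1,1}: 5*2*3*5*2*2*2 = 1200
  clusters <- c(
    TSFA = 1, TMUFA = 1, TPUFA = 1, ARA = 1, n6_n3 = 2,
    DHA = 3, ARA_DHA = 3, PC = 4, PE = 4, PI = 4, SPH = 4,
    Choline = 5, PCho = 6, GPC = 7
  )
  cands <- enumerate_candidates(clusters)
  expect_equal(length(cands), 1200L)
  expect_equal(length(unique(vapply(cands, function(s) paste(sort(s), collapse = ","), ""))), 1200L)
  # one-per-cluster invariant for every candidate
  ok <- vapply(cands, function(s) !anyDuplicated(clusters[s]), logical(1))
  expect_true(all(ok))
  # the empty model is included
  expect_true(any(lengths(cands) == 0))

  expect_equal(length(enumerate_candidates(c(x = 1))), 2L)
})

test_that("adjusted R2 reproduces the published bookkeeping", {
  expect_equal(round(adjusted_r2(0.43, 42, 7), 2), 0.31)
  expect_equal(round(adjusted_r2(0.36, 38, 8), 2), 0.18)
  expect_equal(adjusted_r2(1, 40, 5), 1)
  # monotone in r2, approaches r2 as n grows
  expect_lt(adjusted_r2(0.3, 30, 5), adjusted_r2(0.4, 30, 5))
  expect_lt(abs(adjusted_r2(0.4, 1e6, 5) - 0.4), 1e-5)
  expect_error(adjusted_r2(0.5, 6, 5), class = "milkcog_error_too_small")
})

test_that("best subset matches the exhaustive lm() oracle on random instances", {
  confounders <- c("visit_age_months", "sex", "site", "income_lt75k")
  withr::with_seed(13, {
    for (i in 1:12) {
      nutrients <- paste0("nut", 1:6)
      clusters <- setNames(sample(1:4, 6, replace = TRUE), nutrients)
      d <- make_test_frame(45, nutrients = nutrients, seed = 4000 + i)
      d$y <- rnorm(45) + 0.6 * d$nut1 - 0.4 * d$nut3
      fit <- best_subset_fit(d, "y", clusters, confounders)
      oracle <- oracle_best_subset(d, "y", clusters, confounders)
      expect_setequal(fit$selected, oracle$subset)
      expect_equal(fit$adj_r2, oracle$ar2, tolerance = 1e-10)
    }
  })
})

test_that("selected model dominates every candidate's adjusted R2", {
  d <- make_test_frame(60, nutrients = paste0("n", 1:5), seed = 17)
  d$y <- 0.5 * d$n2 + rnorm(60)
  clusters <- setNames(c(1, 1, 2, 3, 3), paste0("n", 1:5))
  fit <- best_subset_fit(d, "y", clusters)
  y <- as.numeric(scale(d$y))
  for (s in enumerate_candidates(clusters)) {
    rhs <- c(fit$confounders, s)
    cand <- lm(reformulate(rhs, response = "y"), data = cbind(y = y, d))
    ar2 <- adjusted_r2(summary(cand)$r.squared, 60, length(rhs))
    expect_gte(fit$adj_r2 + 1e-10, ar2)
  }
})

test_that("a pure-noise outcome yields near-zero adjusted R2 at large n", {
  clusters <- setNames(
    default_nutrient_panel()$cluster_id,
    default_nutrient_panel()$name
  )
  n <- 5000
  d <- dplyr::bind_cols(
    make_test_frame(n, nutrients = character(0), seed = 19),
    sample_nutrient_matrix(n, seed = 19)
  )
  withr::with_seed(20, d$y <- rnorm(n))
  fr <- standardize_columns(d, default_nutrient_panel()$name)
  fit <- best_subset_fit(fr, "y", clusters)
  expect_lt(fit$adj_r2, 0.01)
})

test_that("nested F-test matches stats::anova and handles edge cases", {
  d <- make_test_frame(50, nutrients = c("x1", "x2"), seed = 23)
  withr::with_seed(24, d$y <- 0.4 * d$x1 + rnorm(50))
  full <- lm(y ~ visit_age_months + sex + x1 + x2, data = d)
  reduced <- lm(y ~ visit_age_months + sex, data = d)
  res <- nested_anova_f(full, reduced)
  ref <- anova(reduced, full)
  expect_equal(res$f_stat, ref$F[2], tolerance = 1e-10)
  expect_equal(res$p_raw, ref$`Pr(>F)`[2], tolerance = 1e-10)

  # identical RSS: F = 0, p = 1
  d$z <- 0 # no-information regressor: F small but not exactly 0; use exact case
  y3 <- c(1, 2, 3)
  f3 <- lm(y3 ~ c(1, 2, 3))
  r3 <- lm(y3 ~ 1)
  # saturated full model: p ~ 0
  sat <- nested_anova_f(f3, r3)
  expect_equal(sat$p_raw, 0)
  expect_true(is.infinite(sat$f_stat))

  same <- lm(y ~ visit_age_months, data = d)
  expect_error(nested_anova_f(same, same), class = "milkcog_error_identical_models")

  # RSS_full == RSS_red exactly (extra regressor orthogonal to residual)
  yy <- c(1, -1, 1, -1)
  xx <- c(1, 1, -1, -1)
  fit_full <- lm(yy ~ xx)
  fit_red <- lm(yy ~ 1)
  res0 <- nested_anova_f(fit_full, fit_red)
  expect_equal(res0$f_stat, 0)
  expect_equal(res0$p_raw, 1)
})

test_that("nested F type-I error is nominal under the null", {
  withr::with_seed(25, {
    p <- replicate(500, {
      n <- 30
      d <- data.frame(c1 = rnorm(n), x = rnorm(n), y = rnorm(n))
      full <- lm(y ~ c1 + x, data = d)
      reduced <- lm(y ~ c1, data = d)
      nested_anova_f(full, reduced)$p_raw
    })
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.025)
})

test_that("joint selection scan adjusts model p-values within the outcome family", {
  cohort <- simulate_cohort(cohort_config(seed = 31))
  fr <- build_analysis_frame(cohort$baseline, "ibq")
  part <- optimal_partition(default_correlation_target())
  fits <- joint_selection_scan(fr, part$selected)
  expect_named(fits, c("ibq_sur", "ibq_neg", "ibq_reg"))
  p_raw <- vapply(fits, function(f) f$p_raw, numeric(1))
  p_adj <- vapply(fits, function(f) f$p_adj, numeric(1))
  keep <- !is.na(p_raw)
  expect_equal(unname(p_adj[keep]), bh_adjust(unname(p_raw[keep])))
  expect_true(all(p_adj >= p_raw, na.rm = TRUE))
  for (f in fits) {
    expect_lte(f$adj_r2, f$r2)
    expect_match(f$post_selection, "anti-conservative")
  }
  tab <- joint_table(fits)
  expect_equal(names(tab), c("row", "ibq_sur", "ibq_neg", "ibq_reg"))
  expect_true("TSFA" %in% tab$row)
})
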