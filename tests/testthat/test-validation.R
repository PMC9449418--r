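# Cross-validation machinery and follow-up prediction.

test_that("correlation t-test: null, threshold and limiting cases", {
  expect_equal(correlation_t_test(0, 10), 1)
  expect_equal(correlation_t_test(0, 1000), 1)
  expect_error(correlation_t_test(0.5, 2), class = "milkcog_error_too_small")
  expect_warning(p1 <- correlation_t_test(1, 10), "limiting")
  expect_equal(p1, 0)

  # agrees with cor.test on ordinary values
  withr::with_seed(2, {
    x <- rnorm(20)
    y <- 0.4 * x + rnorm(20)
  })
  expect_equal(
    correlation_t_test(cor(x, y), 20),
    cor.test(x, y)$p.value,
    tolerance = 1e-12
  )

  # consistent ordering with a permutation oracle on a small toy
  withr::with_seed(3, {
    xa <- rnorm(5)
    ya <- 0.5 * xa + 0.5 * rnorm(5)
    r_obs <- cor(xa, ya)
    perms <- replicate(2000, cor(xa, sample(ya)))
    p_perm <- mean(abs(perms) >= abs(r_obs))
  })
  p_t <- correlation_t_test(r_obs, 5)
  expect_lt(abs(p_t - p_perm), 0.25)
  expect_equal(p_t < 0.5, p_perm < 0.5)

  # the significance threshold solves the quantile equation at n - 2 df
  r_star <- correlation_threshold(38)
  expect_equal(correlation_t_test(r_star, 38), 0.05, tolerance = 1e-10)
  expect_gt(r_star, 0.31)
  expect_lt(r_star, 0.33)
})

test_that("repeated CV is deterministic, pools each subject once, and is exact on noiseless data", {
  d <- make_test_frame(60, nutrients = c("a", "b"), seed = 5)
  d$y <- 2 + 0.8 * d$a - 0.5 * d$b + 0.1 * d$visit_age_months
  cv <- repeated_cv(d, "y", c("a", "b"), reps = 20, seed = 42)
  expect_equal(nrow(cv$repetitions), 20L)
  expect_true(all(abs(cv$repetitions$cor - 1) < 1e-10))
  expect_true(all(cv$repetitions$mse < 1e-20))

  cv2 <- repeated_cv(d, "y", c("a", "b"), reps = 20, seed = 42)
  expect_identical(cv$repetitions, cv2$repetitions)
  cv3 <- repeated_cv(d, "y", c("a", "b"), reps = 20, seed = 43)
  expect_false(identical(cv$repetitions, cv3$repetitions))

  expect_error(
    repeated_cv(d[1:3, ], "y", c("a", "b"), folds = 5, seed = 1),
    class = "milkcog_error_too_small"
  )
})

test_that("null outcomes produce near-nominal CV significance rates", {
  d <- make_test_frame(200, nutrients = c("a", "b", "c"), seed = 6)
  withr::with_seed(7, d$y <- rnorm(200))
  cv <- repeated_cv(d, "y", c("a", "b", "c"), reps = 100, seed = 8)
  expect_lt(abs(cv$fraction_significant - 0.05), 0.07)
  # a null model generalizes worse than it trains on average
  train_mse <- mean(resid(lm(
    scale(y) ~ visit_age_months + sex + site + income_lt75k + a + b + c,
    data = d
  ))^2)
  expect_gt(mean(cv$repetitions$mse), train_mse)
})

test_that("follow-up prediction reproduces exact and null correlations per bin", {
  cohort <- simulate_cohort(cohort_config(seed = 9))
  fr <- build_analysis_frame(cohort$baseline, "msel")
  part <- optimal_partition(default_correlation_target())
  fit <- best_subset_fit(fr, "msel_rl", part$selected)

  fu <- cohort$followup[cohort$followup$instrument == "msel", ]
  res <- followup_predict(fit, fr, fu, observed = "msel_rl")
  expect_equal(res$bin, c("(6,9]", "(9,12]", "(12,18]"))
  expect_equal(res$n, c(27L, 34L, 25L))
  expect_true(all(abs(res$pearson_r) <= 1))
  # age 7.63 months falls in the 6-9 bin
  pred_first <- res$predictions[[1]]
  expect_true(all(pred_first$age > 6 & pred_first$age <= 9))

  # observed == predicted gives r = 1, p ~ 0
  fu_perfect <- res$predictions[[1]]
  fu_exact <- tibble::tibble(
    subject_id = fu_perfect$subject_id,
    visit_age_months = fu_perfect$age,
    msel_rl = fu_perfect$predicted
  )
  res_exact <- suppressWarnings(followup_predict(
    fit, fr, fu_exact,
    observed = "msel_rl",
    bins = tibble::tibble(bin_low = 6, bin_high = 9)
  ))
  expect_equal(res_exact$pearson_r, 1, tolerance = 1e-12)
  expect_equal(res_exact$p_value, 0)

  # orthogonalized toy: observed residualized against predicted gives r = 0
  pred <- fu_perfect$predicted
  obs0 <- resid(lm(rnorm(length(pred)) ~ pred))
  fu_null <- tibble::tibble(
    subject_id = fu_perfect$subject_id,
    visit_age_months = fu_perfect$age,
    msel_rl = obs0 + mean(pred)
  )
  res_null <- followup_predict(
    fit, fr, fu_null,
    observed = "msel_rl",
    bins = tibble::tibble(bin_low = 6, bin_high = 9)
  )
  expect_equal(res_null$pearson_r, 0, tolerance = 1e-10)
  expect_equal(res_null$p_value, 1, tolerance = 1e-8)
})

test_that("follow-up prediction validates bins and subjects", {
  cohort <- simulate_cohort(cohort_config(seed = 12))
  fr <- build_analysis_frame(cohort$baseline, "msel")
  part <- optimal_partition(default_correlation_target())
  fit <- best_subset_fit(fr, "msel_rl", part$selected)
  fu <- cohort$followup[cohort$followup$instrument == "msel", ]

  dup <- dplyr::bind_rows(fu[1, ], fu[1, ])
  expect_error(
    followup_predict(fit, fr, dup, observed = "msel_rl"),
    class = "milkcog_error_duplicate_subject"
  )
  ghost <- fu[1:5, ]
  ghost$subject_id <- paste0("X", 1:5)
  expect_error(
    followup_predict(fit, fr, ghost, observed = "msel_rl"),
    class = "milkcog_error_missing_baseline"
  )
  tiny <- fu[fu$visit_age_months <= 9, ][1:2, ]
  expect_error(
    followup_predict(fit, fr, tiny,
      observed = "msel_rl",
      bins = tibble::tibble(bin_low = 6, bin_high = 9)
    ),
    class = "milkcog_error_too_small"
  )
})

test_that("follow-up correlations decay as injected noise grows", {
  cohort <- simulate_cohort(cohort_config(seed = 15))
  fr <- build_analysis_frame(cohort$baseline, "msel")
  part <- optimal_partition(default_correlation_target())
  fit <- best_subset_fit(fr, "msel_rl", part$selected)
  fu <- cohort$followup[cohort$followup$instrument == "msel", ]
  base <- followup_predict(fit, fr, fu, observed = "msel_rl")
  pred <- dplyr::bind_rows(base$predictions)
  pred <- pred[!duplicated(pred$subject_id), ]

  rs <- vapply(c(0, 2, 20), function(noise_sd) {
    fu2 <- tibble::tibble(
      subject_id = pred$subject_id,
      visit_age_months = pred$age,
      msel_rl = pred$predicted + withr::with_seed(100, rnorm(nrow(pred), 0, noise_sd))
    )
    res <- suppressWarnings(followup_predict(
      fit, fr, fu2,
      observed = "msel_rl",
      bins = tibble::tibble(bin_low = 6, bin_high = 18)
    ))
    res$pearson_r
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_equal(rs[1], 1, tolerance = 1e-12)
})
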