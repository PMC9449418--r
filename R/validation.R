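# Repeated cross-validation and follow-up prediction.
#
# The nutrient set is fixed before CV (selection is not re-run inside folds,
# matching how the selected models were evaluated; the resulting optimism is
# recorded in the result's metadata). Each repetition randomly partitions the
# subjects into 5 folds, refits the coefficients on 4/5, predicts the held-out
# fifth, pools all out-of-fold predictions, and records one Pearson
# correlation and one mean squared error.

#' Significance test for a Pearson correlation
#'
#' Two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. `|r| = 1` is the limiting case `p = 0` (signalled with
#' a warning).
#'
#' @param r Correlation in \[-1, 1\].
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value.
#' @export
#' @examples
#' correlation_t_test(0.5, 20)
correlation_t_test <- function(r, n) {
  if (n < 3) {
    stop_milkcog("correlation test needs n >= 3", class = "milkcog_error_too_small")
  }
  if (abs(r) > 1 + 1e-12) {
    stop_milkcog("r must lie in [-1, 1]", class = "milkcog_error_bad_config")
  }
  if (abs(r) >= 1) {
    warn("|r| = 1: returning the limiting p-value 0")
    return(0)
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), n - 2)
}

#' Critical correlation at a significance level
#'
#' The value `r*` solving the correlation t-test quantile equation at `n - 2`
#' degrees of freedom; correlations above it are significant at `alpha`
#' (two-sided).
#'
#' @param n Number of paired observations.
#' @param alpha Significance level (default 0.05).
#' @return The threshold correlation.
#' @export
#' @examples
#' correlation_threshold(38)
correlation_threshold <- function(n, alpha = 0.05) {
  tq <- stats::qt(1 - alpha / 2, n - 2)
  tq / sqrt(n - 2 + tq^2)
}

#' Repeated k-fold cross-validation of a selected model
#'
#' @param data Analysis frame.
#' @param outcome Outcome column (z-scored internally, as in fitting).
#' @param selected Nutrient columns of the model (fixed; coefficients are
#'   refit per training fold).
#' @param confounders Confounder columns.
#' @param folds Number of folds (default 5).
#' @param reps Number of repetitions (default 100).
#' @param alpha Significance level for the per-repetition correlation test.
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @return Object of class `milk_cv`: per-repetition tibble plus summaries.
#' @export
repeated_cv <- function(data, outcome, selected,
                        confounders = default_confounders(),
                        folds = 5, reps = 100, alpha = 0.05, seed = 1L) {
  assert_columns(data, c(outcome, selected, confounders))
  n <- nrow(data)
  if (n < folds) {
    stop_milkcog("need at least as many rows as folds", class = "milkcog_error_too_small")
  }
  y <- zscore(data[[outcome]], label = outcome)
  x <- cbind(1, as.matrix(data[c(confounders, selected)]))

  run <- function() {
    purrr::map_dfr(seq_len(reps), function(rep) {
      fold <- sample(rep(seq_len(folds), length.out = n))
      pred <- rep(NA_real_, n)
      for (f in seq_len(folds)) {
        test <- fold == f
        fit <- stats::.lm.fit(x[!test, , drop = FALSE], y[!test])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        pred[test] <- x[test, , drop = FALSE] %*% beta
      }
      r <- stats::cor(pred, y)
      tibble(
        rep = rep, cor = r, mse = mean((pred - y)^2),
        # |r| = 1 (noiseless outcome) takes the limiting p = 0 silently here
        p_value = suppressWarnings(correlation_t_test(r, n))
      )
    })
  }
  repetitions <- withr::with_seed(seed, run())
  r_star <- correlation_threshold(n, alpha)
  structure(
    list(
      outcome = outcome, selected = selected, n = n, folds = folds,
      reps = reps, repetitions = repetitions,
      r_star = r_star, alpha = alpha,
      fraction_significant = mean(repetitions$p_value < alpha),
      cor_mean = mean(repetitions$cor),
      cor_ci = unname(stats::quantile(repetitions$cor, c(0.025, 0.975))),
      note = "nutrient set fixed before CV; correlations are optimistic for selection uncertainty"
    ),
    class = "milk_cv"
  )
}

#' @export
print.milk_cv <- function(x, ...) {
  cat(
    "<milk_cv>", x$outcome, ":", x$reps, "reps of", x$folds, "-fold CV, n =", x$n, "\n",
    sprintf(
      " mean r %.3f [%.3f, %.3f], significant in %.0f%% of reps (r* = %.3f)\n",
      x$cor_mean, x$cor_ci[1], x$cor_ci[2],
      100 * x$fraction_significant, x$r_star
    )
  )
  invisible(x)
}

#' @export
tidy.milk_cv <- function(x, ...) x$repetitions

#' @export
glance.milk_cv <- function(x, ...) {
  tibble(
    outcome = x$outcome, n = x$n, folds = x$folds, reps = x$reps,
    cor_mean = x$cor_mean, cor_lo = x$cor_ci[1], cor_hi = x$cor_ci[2],
    mse_mean = mean(x$repetitions$mse),
    fraction_significant = x$fraction_significant, r_star = x$r_star
  )
}

#' Predict follow-up scores from a frozen baseline model
#'
#' Applies the trained model's coefficients to each follow-up subject's
#' baseline nutrient values (standardized with the training means/SDs) and
#' baseline confounders, bins follow-up visits by age, and reports the Pearson
#' correlation between predicted and observed scores per bin with its t-test
#' p-value. By default the baseline age enters the age covariate (the
#' coefficients were trained on baseline ages); set `use_followup_age = TRUE`
#' to use the follow-up visit age instead.
#'
#' @param fit A `milk_fit` from [best_subset_fit()].
#' @param baseline The analysis frame the model was trained on (provides the
#'   frozen standardization via its `raw_*` columns).
#' @param followup Tibble of follow-up observations: `subject_id`,
#'   `visit_age_months` and the observed outcome column.
#' @param observed Name of the observed score column in `followup` (default:
#'   the fit's outcome).
#' @param bins Tibble with `bin_low`, `bin_high` (months); a visit falls in a
#'   bin when `bin_low < age <= bin_high`.
#' @param min_n Smallest usable bin (default 3); smaller bins error.
#' @param use_followup_age Use the follow-up age as the age covariate.
#' @return Tibble of class `milk_followup`: one row per bin with `pearson_r`,
#'   `p_value`, `n`, plus a `predictions` list-column of per-subject tables.
#' @export
followup_predict <- function(fit, baseline, followup,
                             observed = fit$outcome,
                             bins = tibble(
                               bin_low = c(6, 9, 12),
                               bin_high = c(9, 12, 18)
                             ),
                             min_n = 3, use_followup_age = FALSE) {
  stopifnot(inherits(fit, "milk_fit"))
  assert_columns(followup, c("subject_id", "visit_age_months", observed),
    where = "followup"
  )
  assert_columns(baseline, c("subject_id", fit$confounders), where = "baseline")
  followup <- followup[!is.na(followup[[observed]]), ]
  missing_base <- setdiff(followup$subject_id, baseline$subject_id)
  if (length(missing_base) > 0) {
    stop_milkcog(
      sprintf(
        "follow-up subject(s) without baseline records: %s",
        paste(missing_base, collapse = ", ")
      ),
      class = "milkcog_error_missing_baseline"
    )
  }
  # frozen standardization: training mean/sd from the raw_ columns
  base <- baseline
  for (nm in fit$selected) {
    raw_col <- paste0("raw_", nm)
    if (raw_col %in% names(base)) {
      mu <- mean(base[[raw_col]])
      sdv <- stats::sd(base[[raw_col]])
      base[[nm]] <- (base[[raw_col]] - mu) / sdv
    }
  }
  beta <- stats::coef(fit$model)
  names(beta) <- gsub("`", "", names(beta))

  out <- purrr::pmap_dfr(bins, function(bin_low, bin_high) {
    rows <- followup[followup$visit_age_months > bin_low &
      followup$visit_age_months <= bin_high, ]
    if (anyDuplicated(rows$subject_id)) {
      stop_milkcog(
        sprintf("duplicate subject in bin (%g,%g]", bin_low, bin_high),
        class = "milkcog_error_duplicate_subject"
      )
    }
    n <- nrow(rows)
    if (n < min_n) {
      stop_milkcog(
        sprintf("bin (%g,%g] has %d observation(s), fewer than %d", bin_low, bin_high, n, min_n),
        class = "milkcog_error_too_small"
      )
    }
    b <- base[match(rows$subject_id, base$subject_id), ]
    if (use_followup_age && "visit_age_months" %in% fit$confounders) {
      b$visit_age_months <- rows$visit_age_months
    }
    design <- cbind(1, as.matrix(b[c(fit$confounders, fit$selected)]))
    pred <- as.numeric(design %*% beta[c("(Intercept)", fit$confounders, fit$selected)])
    obs <- rows[[observed]]
    r <- stats::cor(pred, obs)
    p <- suppressWarnings(correlation_t_test(r, n))
    tibble(
      bin = sprintf("(%g,%g]", bin_low, bin_high), n = n,
      pearson_r = r, p_value = p,
      predictions = list(tibble(
        subject_id = rows$subject_id,
        age = rows$visit_age_months, predicted = pred, observed = obs
      ))
    )
  })
  class(out) <- c("milk_followup", class(out))
  out
}
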