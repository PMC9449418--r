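# Marginal (single-nutrient) association scans.
#
# Model: outcome ~ 1 + age + sex + site + income + nutrient, fit by ordinary
# least squares with the outcome and the nutrient z-scored and the confounders
# on their raw scale. The nutrient's coefficient is the reported standardized
# coefficient; its CI comes from the t distribution on n - 6 residual degrees
# of freedom (intercept + 4 confounders + 1 nutrient). P-values across the
# nutrient x outcome grid are FDR-adjusted with Benjamini-Hochberg.

default_confounders <- function() c("visit_age_months", "sex", "site", "income_lt75k")

#' Confounder-adjusted association of one nutrient with one outcome
#'
#' @param data Analysis frame (one row per subject).
#' @param outcome,nutrient Column names; both are z-scored internally (a
#'   no-op if already standardized).
#' @param confounders Confounder column names, kept on their raw scale.
#' @param conf_level Confidence level for the coefficient interval.
#' @return One-row tibble: `nutrient`, `outcome`, `std_coef`, `ci_low`,
#'   `ci_high`, `p_raw`, `n`, `df_resid`.
#' @export
fit_adjusted_model <- function(data, outcome, nutrient,
                               confounders = default_confounders(),
                               conf_level = 0.95) {
  assert_columns(data, c(outcome, nutrient, confounders))
  n <- nrow(data)
  k <- length(confounders) + 1
  if (n <= k + 1) {
    stop_milkcog(sprintf("need more than %d rows, got %d", k + 1, n),
      class = "milkcog_error_too_small"
    )
  }
  y <- zscore(data[[outcome]], label = outcome)
  x <- zscore(data[[nutrient]], label = nutrient)
  design <- cbind(1, as.matrix(data[confounders]), x)
  if (qr(design)$rank < ncol(design)) {
    stop_milkcog("design matrix is rank deficient",
      class = "milkcog_error_rank_deficient"
    )
  }
  fit <- stats::lm.fit(design, y)
  df_resid <- n - ncol(design)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df_resid
  xtx_inv <- chol2inv(chol(crossprod(design)))
  se <- sqrt(sigma2 * xtx_inv[ncol(design), ncol(design)])
  coef_x <- unname(fit$coefficients[length(fit$coefficients)])
  tval <- coef_x / se
  p <- 2 * stats::pt(-abs(tval), df_resid)
  halfwidth <- stats::qt(1 - (1 - conf_level) / 2, df_resid) * se
  tibble(
    nutrient = nutrient, outcome = outcome, std_coef = coef_x,
    se = se, ci_low = coef_x - halfwidth, ci_high = coef_x + halfwidth,
    p_raw = p, n = n, df_resid = df_resid
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns the usual monotone BH adjusted p-values, capped at 1. `m` lets the
#' caller adjust within a larger family than the supplied vector (unsupplied
#' family members implicitly have p = 1).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Family size (default `length(p)`).
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_milkcog("p-values must lie in [0, 1]", class = "milkcog_error_bad_p")
  }
  if (m < length(p)) {
    stop_milkcog("family size m cannot be smaller than length(p)",
      class = "milkcog_error_bad_p"
    )
  }
  n <- length(p)
  if (n == 0) {
    return(numeric(0))
  }
  ord <- order(p, decreasing = TRUE)
  ranks <- n:1 # rank of p among the sorted family (largest first)
  adj <- pmin(1, cummin(m / ranks * p[ord]))
  adj[order(ord)]
}

#' Marginal association scan
#'
#' Fits [fit_adjusted_model()] for every nutrient x outcome pair and adds
#' FDR-adjusted p-values. The default family is all pairs in the scan (one
#' instrument's grid); `family = "per_outcome"` adjusts within each outcome's
#' 14 nutrients instead.
#'
#' @param data Analysis frame (see [build_analysis_frame()]).
#' @param nutrients,outcomes Column names to scan.
#' @param confounders Confounder columns.
#' @param family `"scan"` (default) or `"per_outcome"`.
#' @return Tibble of class `milk_marginal`, one row per pair, sorted as
#'   supplied, with `p_adj` added.
#' @export
marginal_scan <- function(data, nutrients = panel_names()$name,
                          outcomes = attr(data, "outcomes"),
                          confounders = default_confounders(),
                          family = c("scan", "per_outcome")) {
  family <- match.arg(family)
  if (length(outcomes) == 0) {
    stop_milkcog("no outcomes to scan", class = "milkcog_error_bad_config")
  }
  grid <- tidyr::expand_grid(outcome = outcomes, nutrient = nutrients)
  res <- purrr::pmap_dfr(grid, function(outcome, nutrient) {
    fit_adjusted_model(data, outcome, nutrient, confounders)
  })
  if (family == "scan") {
    res$p_adj <- bh_adjust(res$p_raw)
  } else {
    res <- res |>
      dplyr::group_by(.data$outcome) |>
      dplyr::mutate(p_adj = bh_adjust(.data$p_raw)) |>
      dplyr::ungroup()
  }
  class(res) <- c("milk_marginal", class(res))
  res
}

#' Wide coefficient table for a marginal scan
#'
#' Formats a scan the way association tables are usually printed: nutrients as
#' rows, outcomes as columns, `coef (p)` strings with significant raw p-values
#' parenthesized.
#'
#' @param scan A `milk_marginal` tibble.
#' @param digits Coefficient digits.
#' @return A wide tibble of character cells.
#' @export
marginal_table <- function(scan, digits = 2) {
  scan |>
    dplyr::mutate(
      cell = ifelse(
        .data$p_raw < 0.05,
        sprintf("%.*f (%.3g)", digits, .data$std_coef, .data$p_raw),
        sprintf("%.*f", digits, .data$std_coef)
      )
    ) |>
    dplyr::select("nutrient", "outcome", "cell") |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "cell")
}
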