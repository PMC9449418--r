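# Standardization, imputation and cohort-description statistics.
#
# Nutrient concentrations are z-scored (mean zero, unit variance) before any
# modelling; standardization statistics are computed within the analysis
# subset at hand (the MSEL and IBQ-R models are fit on different subject
# sets). Confounders are left on their raw scale. The single missing-data rule
# is mean imputation of the household-income indicator.

#' Z-score columns of a table
#'
#' Replaces each named column by its sample z-score and preserves the original
#' under a `raw_` prefix. Constant columns are rejected with an error naming
#' the column.
#'
#' @param data Data frame.
#' @param columns Character vector of numeric column names.
#' @return `data` with standardized columns and added `raw_*` copies.
#' @export
#' @examples
#' standardize_columns(data.frame(x = 1:3), "x")
standardize_columns <- function(data, columns) {
  assert_columns(data, columns)
  for (col in columns) {
    if (!is.numeric(data[[col]])) {
      stop_milkcog(sprintf("column `%s` is not numeric", col),
        class = "milkcog_error_bad_column"
      )
    }
    data[[paste0("raw_", col)]] <- data[[col]]
    data[[col]] <- zscore(data[[col]], label = col)
  }
  data
}

#' Mean-impute a binary indicator with missing values
#'
#' Missing entries are replaced by the mean of the observed entries
#' (fractional values are therefore possible); observed entries are untouched.
#'
#' @param x Numeric vector (typically a 0/1 indicator) with possible `NA`s.
#' @return `x` with `NA`s replaced by the observed mean.
#' @export
#' @examples
#' impute_income(c(1, 0, 0, 1, NA))
impute_income <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) == 0) {
    stop_milkcog("cannot impute: all values are missing",
      class = "milkcog_error_all_missing"
    )
  }
  x[is.na(x)] <- mean(obs)
  x
}

#' Per-nutrient age trends
#'
#' Simple linear regression of each nutrient concentration on visit age;
#' reports the slope and its two-sided t-test p-value.
#'
#' @param data Data frame (>= 3 rows).
#' @param nutrients Nutrient column names (default: the standard panel).
#' @param age_col Age column name (months).
#' @return Tibble with `nutrient`, `slope`, `se`, `p_value`, `n`.
#' @export
nutrient_age_trends <- function(data, nutrients = panel_names()$name,
                                age_col = "visit_age_months") {
  assert_columns(data, c(nutrients, age_col))
  if (nrow(data) < 3) {
    stop_milkcog("age-trend regression needs at least 3 rows",
      class = "milkcog_error_too_small"
    )
  }
  age <- data[[age_col]]
  if (stats::sd(age) == 0) {
    stop_milkcog("age column is constant", class = "milkcog_error_constant_column")
  }
  purrr::map_dfr(nutrients, function(nm) {
    fit <- stats::lm(data[[nm]] ~ age)
    s <- summary(fit)$coefficients
    tibble(
      nutrient = nm, slope = s["age", "Estimate"], se = s["age", "Std. Error"],
      p_value = s["age", "Pr(>|t|)"], n = nrow(data)
    )
  })
}

#' Compare nutrient means between two cohort subsets
#'
#' Welch two-sided two-sample t-test per nutrient between two (possibly
#' overlapping) subject subsets, e.g. the MSEL and IBQ-R analysis sets.
#'
#' @param data Data frame with a subject id column and nutrient columns.
#' @param ids_a,ids_b Subject ids of the two subsets (each >= 2).
#' @param nutrients Nutrient column names.
#' @param id_col Subject id column name.
#' @return Tibble with `nutrient`, `mean_a`, `mean_b`, `t`, `p_value`.
#' @export
compare_cohort_subsets <- function(data, ids_a, ids_b,
                                   nutrients = panel_names()$name,
                                   id_col = "subject_id") {
  assert_columns(data, c(id_col, nutrients))
  a <- data[data[[id_col]] %in% ids_a, ]
  b <- data[data[[id_col]] %in% ids_b, ]
  if (nrow(a) < 2 || nrow(b) < 2) {
    stop_milkcog("each subset needs at least 2 subjects",
      class = "milkcog_error_too_small"
    )
  }
  purrr::map_dfr(nutrients, function(nm) {
    tt <- stats::t.test(a[[nm]], b[[nm]])
    tibble(
      nutrient = nm, mean_a = mean(a[[nm]]), mean_b = mean(b[[nm]]),
      t = unname(tt$statistic), p_value = tt$p.value
    )
  })
}

#' Build the analysis frame for one instrument
#'
#' Filters the baseline table to subjects with the instrument's scores,
#' imputes missing income, z-scores the nutrient columns within that subset,
#' and attaches the composite outcome columns (ELC for MSEL, the three
#' temperament factors for IBQ-R).
#'
#' @param baseline Baseline cohort tibble (schema of [simulate_cohort()]).
#' @param instrument `"msel"` or `"ibq"`.
#' @param nutrients Nutrient column names.
#' @param loadings IBQ-R factor loadings (used when `instrument = "ibq"`).
#' @return Tibble ready for [marginal_scan()] / [best_subset_fit()], with
#'   attribute `outcomes` naming the outcome columns.
#' @export
build_analysis_frame <- function(baseline, instrument = c("msel", "ibq"),
                                 nutrients = panel_names()$name,
                                 loadings = default_ibq_loadings()) {
  instrument <- match.arg(instrument)
  assert_columns(baseline, c(nutrients, "income_lt75k"))
  if (instrument == "msel") {
    assert_columns(baseline, msel_cols())
    frame <- baseline[stats::complete.cases(baseline[msel_cols()]), ]
    frame <- add_elc(frame)
    outcomes <- c("msel_elc", msel_cols())
  } else {
    assert_columns(baseline, ibq_cols())
    frame <- baseline[stats::complete.cases(baseline[ibq_cols()]), ]
    frame <- add_ibq_factors(frame, loadings)
    outcomes <- paste0("ibq_", tolower(names(loadings)[vapply(loadings, is.numeric, logical(1))]))
  }
  frame$income_lt75k <- impute_income(frame$income_lt75k)
  frame <- standardize_columns(frame, nutrients)
  attr(frame, "outcomes") <- outcomes
  frame
}

#' Cohort characteristics table
#'
#' Counts and mean (SD) descriptors per analysis subset, mirroring the usual
#' participants table of a cohort paper.
#'
#' @param cohort A `milk_cohort`.
#' @return Tibble with one row per subset (all, MSEL, IBQ-R) and descriptor
#'   columns.
#' @export
cohort_characteristics <- function(cohort) {
  stopifnot(inherits(cohort, "milk_cohort"))
  b <- cohort$baseline
  subset_row <- function(label, rows) {
    tibble(
      subset = label,
      n = nrow(rows),
      n_male = sum(rows$sex == 1),
      age_mean = mean(rows$visit_age_months),
      age_sd = stats::sd(rows$visit_age_months),
      income_lt75k = sum(rows$income_lt75k == 1, na.rm = TRUE),
      income_missing = sum(is.na(rows$income_lt75k))
    )
  }
  dplyr::bind_rows(
    subset_row("all", b),
    subset_row("msel", b[stats::complete.cases(b[msel_cols()]), ]),
    subset_row("ibq", b[stats::complete.cases(b[ibq_cols()]), ])
  )
}
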