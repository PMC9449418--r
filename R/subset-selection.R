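# Cluster-constrained best-subset regression.
#
# Candidate models contain at most one nutrient per correlation cluster (plus
# the four confounders, which are always included and never count toward the
# constraint). Every candidate is fit by OLS with the outcome z-scored; the
# model maximizing adjusted R-squared wins, with ties broken toward fewer
# nutrients and then lexicographic order. Overall significance is the nested
# ANOVA F-test against the confounder-only baseline; being computed after
# selection, this p-value is anti-conservative and is labelled as such.

#' Enumerate cluster-constrained candidate subsets
#'
#' All nutrient subsets with at most one member per cluster, including the
#' empty set; the count is the product over clusters of (size + 1).
#'
#' @param clusters Named vector mapping nutrient name to cluster id (as from
#'   [cluster_membership()] columns, or [optimal_partition()]'s `selected`).
#' @return List of character vectors (each a candidate nutrient set).
#' @export
#' @examples
#' length(enumerate_candidates(c(a = 1, b = 1, c = 2))) # 3 * 2
enumerate_candidates <- function(clusters) {
  if (is.data.frame(clusters)) {
    clusters <- stats::setNames(clusters$cluster, clusters$nutrient)
  }
  groups <- split(names(clusters), clusters)
  choices <- lapply(groups, function(g) c(NA_character_, g))
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  out <- apply(grid, 1, function(row) unname(row[!is.na(row)]), simplify = FALSE)
  lapply(out, as.character)
}

#' Adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - n_regressors - 1)`; `n_regressors` counts
#' the selected nutrients plus the confounders but not the intercept.
#'
#' @param r2 Coefficient of determination.
#' @param n Sample size.
#' @param n_regressors Number of regressors excluding the intercept.
#' @return Adjusted R-squared.
#' @export
#' @examples
#' adjusted_r2(0.43, 42, 7) # 0.31 to two decimals
adjusted_r2 <- function(r2, n, n_regressors) {
  if (any(n <= n_regressors + 1)) {
    stop_milkcog("adjusted R-squared needs n > n_regressors + 1",
      class = "milkcog_error_too_small"
    )
  }
  1 - (1 - r2) * (n - 1) / (n - n_regressors - 1)
}

# Fast candidate scoring: RSS of OLS on (intercept | confounders | subset).
candidate_rss <- function(y, conf_mat, nutr_mat, subset) {
  design <- cbind(1, conf_mat, nutr_mat[, subset, drop = FALSE])
  fit <- stats::.lm.fit(design, y)
  if (any(is.na(fit$coefficients)) || fit$rank < ncol(design)) {
    return(NA_real_)
  }
  sum(fit$residuals^2)
}

#' Best cluster-constrained subset fit
#'
#' Enumerates the candidates for the given clustering, fits each by OLS
#' (confounders always included, outcome z-scored), and returns the adjusted
#' R-squared argmax with its full coefficient table, AIC, and the nested
#' ANOVA F-test against the confounder-only baseline. Rank-deficient
#' candidates are skipped (never crash the search).
#'
#' @param data Analysis frame with standardized nutrient columns.
#' @param outcome Outcome column name.
#' @param clusters Cluster membership (named vector or tibble); nutrients are
#'   its names.
#' @param confounders Confounder columns, always included.
#' @return Object of class `milk_fit`.
#' @export
best_subset_fit <- function(data, outcome, clusters,
                            confounders = default_confounders()) {
  if (is.data.frame(clusters)) {
    clusters <- stats::setNames(clusters$cluster, clusters$nutrient)
  }
  nutrients <- names(clusters)
  assert_columns(data, c(outcome, nutrients, confounders))
  n <- nrow(data)
  y <- zscore(data[[outcome]], label = outcome)
  conf_mat <- as.matrix(data[confounders])
  nutr_mat <- as.matrix(data[nutrients])
  candidates <- enumerate_candidates(clusters)

  tss <- sum((y - mean(y))^2)
  n_conf <- length(confounders)
  best <- NULL
  best_key <- NULL
  n_skipped <- 0L
  for (subset in candidates) {
    q <- length(subset)
    if (n <= n_conf + q + 1) {
      n_skipped <- n_skipped + 1L
      next
    }
    rss <- candidate_rss(y, conf_mat, nutr_mat, subset)
    if (is.na(rss)) {
      n_skipped <- n_skipped + 1L
      next
    }
    r2 <- 1 - rss / tss
    ar2 <- adjusted_r2(r2, n, n_conf + q)
    key <- list(ar2 = ar2, q = q, subset = paste(sort(subset), collapse = ","))
    better <- is.null(best_key) ||
      key$ar2 > best_key$ar2 + 1e-12 ||
      (abs(key$ar2 - best_key$ar2) <= 1e-12 &&
        (key$q < best_key$q ||
          (key$q == best_key$q && key$subset < best_key$subset)))
    if (better) {
      best <- list(subset = subset, rss = rss, r2 = r2, adj_r2 = ar2, q = q)
      best_key <- key
    }
  }
  if (is.null(best)) {
    stop_milkcog("no candidate model could be fit", class = "milkcog_error_rank_deficient")
  }

  # refit the winner with lm() for the coefficient table and AIC
  design_df <- data.frame(.y = y, data[confounders], data[best$subset], check.names = FALSE)
  full <- stats::lm(
    stats::reformulate(
      sprintf("`%s`", c(confounders, best$subset)),
      response = ".y"
    ),
    data = design_df
  )
  reduced <- stats::lm(
    stats::reformulate(sprintf("`%s`", confounders), response = ".y"),
    data = design_df
  )
  s <- summary(full)$coefficients
  coef_tbl <- tibble(
    term = rownames(s),
    estimate = s[, "Estimate"], std_error = s[, "Std. Error"],
    statistic = s[, "t value"], p_value = s[, "Pr(>|t|)"]
  )
  coef_tbl$term <- gsub("`", "", coef_tbl$term)
  anova_res <- if (best$q >= 1) {
    nested_anova_f(full, reduced)
  } else {
    list(f_stat = NA_real_, p_raw = NA_real_, df1 = 0L, df2 = full$df.residual)
  }
  structure(
    list(
      outcome = outcome, selected = best$subset, q = best$q,
      clusters = clusters, confounders = confounders, n = n,
      r2 = best$r2, adj_r2 = best$adj_r2, aic = stats::AIC(full),
      coefficients = coef_tbl,
      f_stat = anova_res$f_stat, p_raw = anova_res$p_raw,
      df1 = anova_res$df1, df2 = anova_res$df2,
      p_adj = NA_real_,
      n_candidates = length(candidates), n_skipped = n_skipped,
      post_selection = "F-test computed after subset selection; anti-conservative",
      model = full, reduced = reduced
    ),
    class = "milk_fit"
  )
}

#' Nested ANOVA F-test of a full against a reduced model
#'
#' `F = ((RSS_red - RSS_full) / q) / (RSS_full / df_full)` with `q` the number
#' of additional regressors; p-value from the F distribution. A saturated full
#' model (zero residual variance) returns `F = Inf`, `p = 0`.
#'
#' @param full,reduced Fitted `lm` objects; the reduced model's regressors
#'   must be a subset of the full model's.
#' @return List with `f_stat`, `p_raw`, `df1`, `df2`.
#' @export
nested_anova_f <- function(full, reduced) {
  if (inherits(full, "milk_fit")) {
    if (missing(reduced)) reduced <- full$reduced
    full <- full$model
  }
  rss_full <- sum(stats::residuals(full)^2)
  rss_red <- sum(stats::residuals(reduced)^2)
  df_full <- full$df.residual
  q <- reduced$df.residual - df_full
  if (q < 1) {
    stop_milkcog("full and reduced models have the same regressors",
      class = "milkcog_error_identical_models"
    )
  }
  if (rss_full <= .Machine$double.eps * rss_red || df_full == 0) {
    if (rss_red - rss_full <= 0) {
      return(list(f_stat = 0, p_raw = 1, df1 = q, df2 = df_full))
    }
    return(list(f_stat = Inf, p_raw = 0, df1 = q, df2 = df_full))
  }
  f <- ((rss_red - rss_full) / q) / (rss_full / df_full)
  f <- max(f, 0)
  list(
    f_stat = f, p_raw = stats::pf(f, q, df_full, lower.tail = FALSE),
    df1 = q, df2 = df_full
  )
}

#' Fit the selected models for every outcome of an instrument
#'
#' Runs [best_subset_fit()] per outcome and adds FDR-adjusted model p-values
#' within the instrument's outcome family.
#'
#' @param data Analysis frame with attribute `outcomes` (or pass `outcomes`).
#' @param clusters Cluster membership.
#' @param outcomes Outcome column names.
#' @param confounders Confounder columns.
#' @return Named list of `milk_fit` objects with `p_adj` filled in.
#' @export
joint_selection_scan <- function(data, clusters, outcomes = attr(data, "outcomes"),
                                 confounders = default_confounders()) {
  fits <- lapply(outcomes, function(oc) best_subset_fit(data, oc, clusters, confounders))
  names(fits) <- outcomes
  p <- vapply(fits, function(f) f$p_raw, numeric(1))
  adj <- rep(NA_real_, length(p))
  adj[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  for (i in seq_along(fits)) fits[[i]]$p_adj <- adj[i]
  fits
}

#' @export
print.milk_fit <- function(x, ...) {
  cat(
    "<milk_fit>", x$outcome, "~ confounders +",
    if (x$q == 0) "(no nutrients)" else paste(x$selected, collapse = " + "), "\n"
  )
  cat(sprintf(
    "  R2 %.3f  adj R2 %.3f  F %.2f (p %.3g, post-selection)  n %d\n",
    x$r2, x$adj_r2, x$f_stat, x$p_raw, x$n
  ))
  invisible(x)
}

#' @export
tidy.milk_fit <- function(x, ...) {
  out <- x$coefficients
  out$selected_nutrient <- out$term %in% x$selected
  out
}

#' @export
glance.milk_fit <- function(x, ...) {
  tibble(
    outcome = x$outcome, r2 = x$r2, adj_r2 = x$adj_r2, aic = x$aic,
    f_stat = x$f_stat, p_raw = x$p_raw, p_adj = x$p_adj,
    q = x$q, n = x$n, n_candidates = x$n_candidates
  )
}

#' Published-style joint regression table
#'
#' One column per outcome, rows for R², adjusted R², raw/adjusted model
#' p-values, each nutrient (dash when not selected) and the confounders.
#'
#' @param fits Named list of `milk_fit` objects (one per outcome).
#' @param nutrients Row order for the nutrient block.
#' @return Tibble of character cells.
#' @export
joint_table <- function(fits, nutrients = panel_names()$name) {
  cols <- lapply(fits, function(f) {
    coefs <- f$coefficients
    cell <- function(term) {
      i <- match(term, coefs$term)
      if (is.na(i)) {
        return("-")
      }
      sprintf("%.2f (%.2g)", coefs$estimate[i], coefs$p_value[i])
    }
    c(
      r_squared = sprintf("%.2f", f$r2),
      adj_r_squared = sprintf("%.2f", f$adj_r2),
      p_raw = sprintf("%.2g", f$p_raw),
      p_adj = sprintf("%.2g", f$p_adj),
      stats::setNames(
        vapply(nutrients, function(nm) {
          if (nm %in% f$selected) cell(nm) else "-"
        }, character(1)), nutrients
      ),
      stats::setNames(
        vapply(f$confounders, cell, character(1)), f$confounders
      )
    )
  })
  out <- tibble(row = names(cols[[1]]))
  for (oc in names(cols)) out[[oc]] <- unname(cols[[oc]])
  out
}
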