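# ggplot2 displays for each result type.

#' @importFrom ggplot2 ggplot aes geom_tile geom_point geom_line geom_boxplot
#'   geom_hline geom_vline geom_errorbarh geom_abline geom_text facet_wrap
#'   labs scale_fill_gradient2 theme_minimal
NULL

#' Plot a marginal association scan
#'
#' Heatmap of standardized coefficients; cells with raw p < 0.05 are starred,
#' FDR-significant cells doubly so.
#'
#' @param object A `milk_marginal` from [marginal_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.milk_marginal <- function(object, ...) {
  df <- as_tibble(object)
  df$stars <- ifelse(df$p_adj < 0.05, "**", ifelse(df$p_raw < 0.05, "*", ""))
  ggplot(df, aes(x = .data$outcome, y = .data$nutrient, fill = .data$std_coef)) +
    geom_tile() +
    geom_text(aes(label = .data$stars), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(fill = "std. coef", x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot a nutrient correlation matrix
#'
#' @param object A `milk_corr` from [pairwise_correlations()].
#' @param ... Unused.
#' @return A ggplot heatmap with significance stars.
#' @export
autoplot.milk_corr <- function(object, ...) {
  df <- tidy(object)
  df$stars <- ifelse(df$p_adj < 0.05, "**", ifelse(df$p_raw < 0.05, "*", ""))
  ggplot(df, aes(x = .data$var1, y = .data$var2, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = .data$stars), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot the Dunn-index profile of the threshold partitions
#'
#' Dunn index against number of clusters for every single-linkage cut, with
#' the selected partition highlighted.
#'
#' @param object A `milk_partition` from [optimal_partition()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.milk_partition <- function(object, ...) {
  df <- object$solutions[!is.na(object$solutions$dunn), ]
  ggplot(df, aes(x = .data$k, y = .data$dunn)) +
    geom_line() +
    geom_point(aes(colour = .data$selected), size = 2) +
    labs(x = "number of clusters", y = "Dunn index", colour = "selected") +
    theme_minimal()
}

#' Plot a fitted joint model's coefficients
#'
#' @param object A `milk_fit` from [best_subset_fit()].
#' @param ... Unused.
#' @return A ggplot forest-style coefficient plot.
#' @export
autoplot.milk_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "(Intercept)", ]
  df$lo <- df$estimate - 1.96 * df$std_error
  df$hi <- df$estimate + 1.96 * df$std_error
  ggplot(df, aes(x = .data$estimate, y = .data$term, colour = .data$selected_nutrient)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$lo, xmax = .data$hi), height = 0.2) +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(
      x = "standardized coefficient", y = NULL, colour = "nutrient",
      title = object$outcome
    ) +
    theme_minimal()
}

#' Plot repeated cross-validation correlations
#'
#' Boxplot of per-repetition out-of-fold prediction correlations with the
#' significance threshold line.
#'
#' @param object A `milk_cv` (or list of them) from [repeated_cv()].
#' @param ... Further `milk_cv` objects to show side by side.
#' @return A ggplot.
#' @export
autoplot.milk_cv <- function(object, ...) {
  objs <- c(list(object), Filter(function(o) inherits(o, "milk_cv"), list(...)))
  df <- dplyr::bind_rows(
    lapply(objs, function(o) dplyr::mutate(o$repetitions, outcome = o$outcome))
  )
  ggplot(df, aes(x = .data$outcome, y = .data$cor)) +
    geom_boxplot() +
    geom_hline(yintercept = object$r_star, linetype = 2, colour = "purple") +
    labs(x = NULL, y = "prediction correlation") +
    theme_minimal()
}

#' Plot follow-up predictions
#'
#' Observed against predicted scores, one panel per age bin, annotated with
#' the per-bin Pearson correlation.
#'
#' @param object A `milk_followup` from [followup_predict()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.milk_followup <- function(object, ...) {
  df <- tidyr::unnest(
    dplyr::select(as_tibble(object), "bin", "pearson_r", "predictions"),
    "predictions"
  )
  df$label <- sprintf("%s  r = %.2f", df$bin, df$pearson_r)
  ggplot(df, aes(x = .data$predicted, y = .data$observed)) +
    geom_point() +
    facet_wrap(~label, scales = "free") +
    labs(x = "predicted score", y = "observed score") +
    theme_minimal()
}
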