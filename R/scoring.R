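# Composite outcome scores.
#
# MSEL: the early learning composite (ELC) is the sum of the four non-motor
# subscale T-scores (visual reception, fine motor, receptive language,
# expressive language); gross motor is excluded by definition.
#
# IBQ-R: the three temperament factors (surgency/extraversion, negative
# affectivity, orienting/regulation) are weighted averages of the 14 subscale
# means. The factor loadings published with the instrument are not
# redistributable, so the package ships a synthetic placeholder loading table
# with the standard subscale-to-factor assignment (6/4/4) and plausible
# weights; users supply real loadings for real data.

#' Early learning composite score
#'
#' Sums the four included MSEL subscale T-scores; the gross-motor score is
#' accepted (for interface symmetry) but has no effect. Missing subscales
#' propagate to a missing composite with a warning.
#'
#' @param vr,fm,rl,el Visual reception, fine motor, receptive and expressive
#'   language T-scores (vectors recycle as usual).
#' @param gm Gross motor T-score; ignored.
#' @return Numeric vector `vr + fm + rl + el`.
#' @export
#' @examples
#' compute_elc(50, 50, 50, 50, gm = 99)
compute_elc <- function(vr, fm, rl, el, gm = NULL) {
  out <- vr + fm + rl + el
  if (anyNA(out)) {
    warn(sprintf(
      "%d composite value(s) missing because a subscale is missing",
      sum(is.na(out))
    ))
  }
  out
}

#' Add the ELC column to a cohort table
#'
#' @param data Data frame with MSEL subscale columns.
#' @param prefix Column-name prefix (default `"msel_"`).
#' @return `data` with an added `msel_elc` column.
#' @export
add_elc <- function(data, prefix = "msel_") {
  cols <- paste0(prefix, c("vr", "fm", "rl", "el"))
  assert_columns(data, cols)
  keep <- stats::complete.cases(data[cols])
  out <- rep(NA_real_, nrow(data))
  if (any(keep)) {
    out[keep] <- rowSums(data[keep, cols])
  }
  data[[paste0(prefix, "elc")]] <- out
  data
}

#' Synthetic placeholder IBQ-R factor loadings
#'
#' Reads the bundled loading table: 14 subscales assigned to surgency (6),
#' negative affectivity (4) and orienting/regulation (4) with plausible
#' synthetic weights. These are placeholders for testing the scoring
#' machinery, not the instrument's published loadings.
#'
#' @return Tibble with columns `subscale`, `label`, `SUR`, `NEG`, `REG`.
#' @export
default_ibq_loadings <- function() {
  path <- system.file("extdata", "ibq_factor_loadings_synthetic.csv",
    package = "milkcog", mustWork = TRUE
  )
  as_tibble(utils::read.csv(path))
}

#' IBQ-R temperament factors from subscale means
#'
#' Each factor is the weighted average of the subscales with nonzero weight in
#' its loading column: `sum(w_i * s_i) / sum(w_i)`. Set `normalize = FALSE`
#' for a plain weighted sum.
#'
#' @param subscales Numeric matrix or data frame (subjects x 14 subscales), or
#'   a single length-14 vector.
#' @param loadings Loading table as from [default_ibq_loadings()]: one row per
#'   subscale and one numeric column per factor (plus optional `subscale` /
#'   `label` columns). Row order must match the subscale order.
#' @param normalize Divide by the weight sum (default TRUE, a weighted
#'   average).
#' @return Tibble with one column per factor (lower-case names), one row per
#'   subject.
#' @export
#' @examples
#' compute_ibq_factors(matrix(rnorm(28, 4), nrow = 2))
compute_ibq_factors <- function(subscales, loadings = default_ibq_loadings(),
                                normalize = TRUE) {
  if (is.vector(subscales) && is.numeric(subscales)) {
    subscales <- matrix(subscales, nrow = 1)
  }
  subscales <- as.matrix(subscales)
  factor_cols <- names(loadings)[vapply(loadings, is.numeric, logical(1))]
  w <- as.matrix(loadings[, factor_cols])
  if (nrow(w) != ncol(subscales)) {
    stop_milkcog(
      sprintf(
        "%d subscale columns but %d loading rows", ncol(subscales), nrow(w)
      ),
      class = "milkcog_error_length_mismatch"
    )
  }
  if (any(colSums(w != 0) == 0)) {
    stop_milkcog("every factor needs at least one nonzero loading",
      class = "milkcog_error_bad_loadings"
    )
  }
  scores <- subscales %*% w
  if (normalize) {
    scores <- sweep(scores, 2, colSums(w), `/`)
  }
  colnames(scores) <- tolower(factor_cols)
  as_tibble(as.data.frame(scores))
}

#' Add IBQ-R factor columns to a cohort table
#'
#' @param data Data frame with subscale columns `ibq_01` ... `ibq_14`.
#' @param loadings,normalize Passed to [compute_ibq_factors()].
#' @return `data` with added `ibq_sur`, `ibq_neg`, `ibq_reg` columns (missing
#'   for subjects with any missing subscale).
#' @export
add_ibq_factors <- function(data, loadings = default_ibq_loadings(),
                            normalize = TRUE) {
  cols <- loadings$subscale
  assert_columns(data, cols)
  keep <- stats::complete.cases(data[cols])
  factor_cols <- tolower(names(loadings)[vapply(loadings, is.numeric, logical(1))])
  for (fc in factor_cols) data[[paste0("ibq_", fc)]] <- NA_real_
  if (any(keep)) {
    scores <- compute_ibq_factors(data[keep, cols], loadings, normalize)
    for (fc in factor_cols) {
      data[[paste0("ibq_", fc)]][keep] <- scores[[fc]]
    }
  }
  data
}
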