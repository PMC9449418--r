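#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Stop with a classed condition so callers can test failure modes precisely.
stop_milkcog <- function(message, class, ...) {
  abort(message, class = c(class, "milkcog_error"), ...)
}

assert_columns <- function(data, columns, where = "data") {
  missing <- setdiff(columns, names(data))
  if (length(missing) > 0) {
    stop_milkcog(
      sprintf(
        "column%s %s missing from %s",
        if (length(missing) > 1) "s" else "",
        paste0("`", missing, "`", collapse = ", "), where
      ),
      class = "milkcog_error_missing_column"
    )
  }
  invisible(TRUE)
}

# Sample z-score; errors on zero variance naming the column.
zscore <- function(x, label = "x") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop_milkcog(
      sprintf("column `%s` has zero variance and cannot be standardized", label),
      class = "milkcog_error_constant_column"
    )
  }
  (x - mean(x)) / s
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
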