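# Correlation structure of the nutrient panel.
#
# Nutrients are clustered by single linkage on the distance 1 - r (signed
# Pearson correlation; a config flag offers 1 - |r|). A threshold partition at
# Tc contains the connected components of the graph whose edges are nutrient
# pairs with r >= Tc; this is identical to cutting the single-linkage merge
# tree at height 1 - Tc. The number of clusters is chosen by maximizing the
# Dunn index (minimum single-linkage separation between clusters divided by
# maximum within-cluster diameter, singletons contributing diameter zero).
# The inclusive edge rule (r >= Tc, not r > Tc) is what makes the threshold
# intervals half-open on the left, matching how the stability intervals are
# conventionally reported, and makes the graph and tree constructions agree
# exactly at merge heights.

#' Pairwise nutrient correlations with significance
#'
#' @param data Data frame (>= 3 rows).
#' @param columns Nutrient column names.
#' @return Object of class `milk_corr`: list with matrices `r`, `p_raw`,
#'   `p_adj` (BH over the upper triangle) and the sample size `n`.
#' @export
pairwise_correlations <- function(data, columns = panel_names()$name) {
  assert_columns(data, columns)
  if (nrow(data) < 3) {
    stop_milkcog("correlations need at least 3 rows", class = "milkcog_error_too_small")
  }
  x <- as.matrix(data[columns])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop_milkcog(
      sprintf("constant column(s): %s", paste(columns[sds == 0], collapse = ", ")),
      class = "milkcog_error_constant_column"
    )
  }
  r <- stats::cor(x)
  n <- nrow(x)
  p <- matrix(NA_real_, ncol(r), ncol(r), dimnames = dimnames(r))
  ut <- upper.tri(r)
  p[ut] <- vapply(r[ut], function(rr) correlation_t_test(rr, n), numeric(1))
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  p_adj <- p
  p_adj[ut] <- bh_adjust(p[ut])
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  structure(list(r = r, p_raw = p, p_adj = p_adj, n = n), class = "milk_corr")
}

#' @export
print.milk_corr <- function(x, ...) {
  cat("<milk_corr>", ncol(x$r), "variables, n =", x$n, "\n")
  print(round(x$r, 2))
  invisible(x)
}

#' @export
tidy.milk_corr <- function(x, ...) {
  labs <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    var1 = labs[idx[, 1]], var2 = labs[idx[, 2]],
    r = x$r[idx], p_raw = x$p_raw[idx], p_adj = x$p_adj[idx]
  )
}

# Accept a milk_corr, a correlation matrix, or anything coercible.
as_corr_matrix <- function(corr) {
  r <- if (inherits(corr, "milk_corr")) corr$r else as.matrix(corr)
  validate_correlation_target(r, require_psd = FALSE)
  if (is.null(colnames(r))) {
    colnames(r) <- rownames(r) <- paste0("V", seq_len(ncol(r)))
  }
  r
}

corr_distance <- function(r, absolute = FALSE) {
  d <- if (absolute) 1 - abs(r) else 1 - r
  diag(d) <- 0
  d
}

#' Threshold partition of the nutrient correlation graph
#'
#' Clusters are the connected components of the graph whose edges join pairs
#' with correlation at least `tc` (equivalently: the single-linkage tree cut
#' at distance `1 - tc`). Implemented directly as graph components via
#' union-find; the tree-cut route is available for cross-checking via
#' [merge_tree()] and `stats::cutree`.
#'
#' @param corr A `milk_corr` or correlation matrix.
#' @param tc Correlation threshold in (-1, 1).
#' @param absolute Cluster on `|r|` instead of signed `r`.
#' @return Named integer vector: cluster id per nutrient (ids ordered by first
#'   appearance).
#' @export
single_linkage_clusters <- function(corr, tc, absolute = FALSE) {
  if (tc <= -1 || tc >= 1) {
    stop_milkcog("tc must lie in (-1, 1)", class = "milkcog_error_bad_config")
  }
  r <- as_corr_matrix(corr)
  if (absolute) r <- abs(r)
  p <- ncol(r)
  parent <- seq_len(p)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (r[i, j] >= tc) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(p), find, integer(1))
  labels <- match(roots, unique(roots))
  names(labels) <- colnames(r)
  labels
}

#' Single-linkage merge tree of the nutrient distances
#'
#' @param corr A `milk_corr` or correlation matrix.
#' @param absolute Use `1 - |r|` distances.
#' @return An `hclust` object (single linkage on `1 - r`).
#' @export
merge_tree <- function(corr, absolute = FALSE) {
  r <- as_corr_matrix(corr)
  d <- corr_distance(r, absolute)
  stats::hclust(stats::as.dist(d), method = "single")
}

#' Dunn index of a partition
#'
#' Minimum between-cluster single-linkage distance divided by maximum
#' within-cluster diameter (largest intra-cluster distance; singletons
#' contribute zero). Undefined for fewer than two clusters, and for
#' all-singleton partitions (zero maximum diameter), which are signalled with
#' classed errors.
#'
#' @param dist_matrix Symmetric distance matrix.
#' @param labels Cluster membership vector (length `ncol(dist_matrix)`).
#' @return The Dunn index (positive scalar).
#' @export
dunn_index <- function(dist_matrix, labels) {
  dist_matrix <- as.matrix(dist_matrix)
  if (length(labels) != ncol(dist_matrix)) {
    stop_milkcog("labels length must match the distance matrix",
      class = "milkcog_error_length_mismatch"
    )
  }
  ks <- unique(labels)
  if (length(ks) < 2) {
    stop_milkcog("Dunn index needs at least two clusters",
      class = "milkcog_error_dunn_undefined"
    )
  }
  diam <- max(vapply(ks, function(k) {
    idx <- which(labels == k)
    if (length(idx) < 2) 0 else max(dist_matrix[idx, idx])
  }, numeric(1)))
  if (diam == 0) {
    stop_milkcog("Dunn index undefined: all clusters are singletons",
      class = "milkcog_error_dunn_undefined"
    )
  }
  sep <- min(vapply(seq_along(ks)[-length(ks)], function(a) {
    min(vapply(seq(a + 1, length(ks)), function(b) {
      min(dist_matrix[labels == ks[a], labels == ks[b], drop = FALSE])
    }, numeric(1)))
  }, numeric(1)))
  sep / diam
}

#' All threshold partitions with their Dunn indices
#'
#' Cuts the single-linkage tree between every pair of consecutive merge
#' heights, records each distinct partition with the correlation-threshold
#' interval `(tc_low, tc_high]` over which it is produced, computes its Dunn
#' index (NA where undefined), and selects the argmax. Ties are broken toward
#' fewer clusters, then toward the lower threshold.
#'
#' @param corr A `milk_corr` or correlation matrix.
#' @param absolute Use `1 - |r|` distances.
#' @return Object of class `milk_partition`: list with `solutions` (tibble:
#'   `k`, `tc_low`, `tc_high`, `dunn`, `selected`, `labels` list-column),
#'   `selected` (the winning labels vector), `tree` (hclust), and the
#'   distance matrix.
#' @export
optimal_partition <- function(corr, absolute = FALSE) {
  r <- as_corr_matrix(corr)
  d <- corr_distance(r, absolute)
  hc <- merge_tree(r, absolute)
  heights <- sort(unique(hc$height))
  p <- ncol(r)
  # cut levels: below the first merge (all singletons) and after each merge
  cut_heights <- c(-Inf, heights)
  upper <- c(heights, Inf)
  sols <- purrr::map_dfr(seq_along(cut_heights), function(i) {
    h <- cut_heights[i]
    labels <- if (is.infinite(h)) {
      stats::setNames(seq_len(p), colnames(r))
    } else {
      stats::cutree(hc, h = h)
    }
    dunn <- tryCatch(dunn_index(d, labels), milkcog_error_dunn_undefined = function(e) NA_real_)
    tibble(
      k = length(unique(labels)),
      tc_low = max(-1, 1 - upper[i]), tc_high = min(1, 1 - h),
      dunn = dunn, labels = list(labels)
    )
  })
  ok <- which(!is.na(sols$dunn))
  if (length(ok) == 0) {
    stop_milkcog("no partition has a defined Dunn index",
      class = "milkcog_error_dunn_undefined"
    )
  }
  # argmax Dunn; ties -> smaller k, then lower threshold
  best <- ok[order(-sols$dunn[ok], sols$k[ok], sols$tc_low[ok])][1]
  sols$selected <- seq_len(nrow(sols)) == best
  structure(
    list(
      solutions = sols, selected = sols$labels[[best]],
      k = sols$k[best], dunn = sols$dunn[best],
      tc_interval = c(sols$tc_low[best], sols$tc_high[best]),
      tree = hc, dist = d
    ),
    class = "milk_partition"
  )
}

#' @export
print.milk_partition <- function(x, ...) {
  cat(
    "<milk_partition> selected k =", x$k,
    sprintf(
      "(Dunn %.3f, stable for %.2f < Tc <= %.2f)\n",
      x$dunn, x$tc_interval[1], x$tc_interval[2]
    )
  )
  groups <- split(names(x$selected), x$selected)
  for (g in seq_along(groups)) {
    cat("  group", g, ":", paste(groups[[g]], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.milk_partition <- function(x, ...) {
  x$solutions |>
    dplyr::mutate(
      members = purrr::map_chr(.data$labels, function(l) {
        paste(vapply(
          split(names(l), l), paste,
          character(1),
          collapse = ","
        ), collapse = " | ")
      })
    ) |>
    dplyr::select("k", "tc_low", "tc_high", "dunn", "selected", "members")
}

#' Cluster membership as a tidy table
#'
#' @param partition A `milk_partition`.
#' @return Tibble with `nutrient` and `cluster`.
#' @export
cluster_membership <- function(partition) {
  stopifnot(inherits(partition, "milk_partition"))
  tibble(
    nutrient = names(partition$selected),
    cluster = unname(partition$selected)
  )
}

#' Minimum spanning tree of the nutrient correlation graph
#'
#' Prim's algorithm on the distance `1 - r`. Removing all tree edges with
#' `r < tc` leaves components identical to [single_linkage_clusters()] at
#' `tc` (the classical single-linkage / MST equivalence).
#'
#' @param corr A `milk_corr` or correlation matrix.
#' @param absolute Use `1 - |r|` distances.
#' @return Tibble with `p - 1` rows: `from`, `to`, `r`, `distance`.
#' @export
minimum_spanning_tree <- function(corr, absolute = FALSE) {
  r <- as_corr_matrix(corr)
  d <- corr_distance(r, absolute)
  p <- ncol(d)
  labs <- colnames(d)
  if (p == 1) {
    return(tibble(from = character(), to = character(), r = numeric(), distance = numeric()))
  }
  in_tree <- c(TRUE, rep(FALSE, p - 1))
  best_dist <- d[, 1]
  best_from <- rep(1L, p)
  edges <- vector("list", p - 1)
  for (step in seq_len(p - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_dist[cand])]
    i <- best_from[j]
    edges[[step]] <- tibble(
      from = labs[i], to = labs[j], r = r[i, j], distance = d[i, j]
    )
    in_tree[j] <- TRUE
    relax <- !in_tree & d[, j] < best_dist
    best_dist[relax] <- d[relax, j]
    best_from[relax] <- j
  }
  dplyr::bind_rows(edges)
}
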