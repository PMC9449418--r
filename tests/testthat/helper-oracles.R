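# Independent brute-force oracles used to cross-check the implementation.

# Connected components of the graph with edges {r_ij >= tc}: breadth-first
# search, independent of the union-find in the package.
oracle_components <- function(r, tc) {
  p <- ncol(r)
  adj <- r >= tc
  diag(adj) <- TRUE
  labels <- rep(NA_integer_, p)
  cluster <- 0L
  for (start in seq_len(p)) {
    if (!is.na(labels[start])) next
    cluster <- cluster + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(labels[v])) next
      labels[v] <- cluster
      queue <- c(queue, which(adj[v, ] & is.na(labels)))
    }
  }
  names(labels) <- colnames(r)
  labels
}

# Kruskal's algorithm by hand (sort edges, add if it joins two components).
oracle_mst_kruskal <- function(d) {
  p <- ncol(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2], w = d[idx])
  edges <- edges[order(edges$w), ]
  comp <- seq_len(p)
  kept <- list()
  for (e in seq_len(nrow(edges))) {
    ci <- comp[edges$i[e]]
    cj <- comp[edges$j[e]]
    if (ci != cj) {
      comp[comp == cj] <- ci
      kept[[length(kept) + 1]] <- edges[e, ]
    }
  }
  do.call(rbind, kept)
}

# Step-up BH definition: adj_(i) = min_{j >= i} p_(j) * m / j, computed by
# explicit double loop.
oracle_bh <- function(p, m = length(p)) {
  ord <- order(p)
  sorted <- p[ord]
  n <- length(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(sorted[i:n] * m / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Exhaustive cluster-constrained best subset by recursive enumeration plus
# plain lm() refits (independent of the package's search).
oracle_best_subset <- function(data, outcome, clusters, confounders) {
  groups <- split(names(clusters), clusters)
  subsets <- list(character(0))
  for (g in groups) {
    subsets <- c(
      subsets,
      unlist(lapply(g, function(nm) lapply(subsets, function(s) c(s, nm))),
        recursive = FALSE
      )
    )
  }
  y <- as.numeric(scale(data[[outcome]]))
  n <- nrow(data)
  best <- NULL
  for (s in subsets) {
    rhs <- c(confounders, s)
    fit <- stats::lm(
      stats::reformulate(sprintf("`%s`", rhs), response = "y"),
      data = cbind(y = y, data)
    )
    if (any(is.na(stats::coef(fit)))) next
    r2 <- summary(fit)$r.squared
    k <- length(rhs)
    if (n <= k + 1) next
    ar2 <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
    key <- paste(sort(s), collapse = ",")
    if (is.null(best) || ar2 > best$ar2 + 1e-12 ||
      (abs(ar2 - best$ar2) <= 1e-12 &&
        (length(s) < length(best$subset) ||
          (length(s) == length(best$subset) && key < best$key)))) {
      best <- list(subset = s, ar2 = ar2, key = key)
    }
  }
  best
}

# Components of a node set given a kept-edge table (from, to).
oracle_components_from_edges <- function(nodes, edges) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      a <- comp[edges$from[e]]
      b <- comp[edges$to[e]]
      if (a != b) comp[comp == b] <- a
    }
  }
  stats::setNames(match(comp, unique(comp)), nodes)
}

# Random correlation-like symmetric matrix with unit diagonal (not
# necessarily PSD; fine for clustering tests, which only read the entries).
random_corr_matrix <- function(p, seed) {
  withr::with_seed(seed, {
    r <- matrix(stats::runif(p * p, -0.3, 0.95), p, p)
    r[lower.tri(r)] <- t(r)[lower.tri(r)]
    diag(r) <- 1
    colnames(r) <- rownames(r) <- paste0("V", seq_len(p))
    r
  })
}

# Small analysis-style frame: confounders plus independent standardized
# nutrient columns, for regression-level tests.
make_test_frame <- function(n, nutrients = c("a", "b", "c"), seed = 1) {
  withr::with_seed(seed, {
    d <- tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      visit_age_months = stats::runif(n, 1, 6),
      sex = stats::rbinom(n, 1, 0.4),
      site = stats::rbinom(n, 1, 0.5),
      income_lt75k = stats::rbinom(n, 1, 0.35)
    )
    for (nm in nutrients) d[[nm]] <- stats::rnorm(n)
    d
  })
}
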