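# Correlation clustering: threshold partitions, Dunn index, MST.

test_that("pairwise correlations handle exact, duplicated and opposed columns", {
  d <- data.frame(a = c(1, 2, 4, 3, 6))
  d$b <- d$a
  d$c <- -d$a
  corr <- suppressWarnings(pairwise_correlations(d, c("a", "b", "c")))
  expect_equal(corr$r["a", "b"], 1)
  expect_equal(corr$r["a", "c"], -1)
  expect_equal(diag(corr$r), c(a = 1, b = 1, c = 1))
  expect_equal(corr$r, t(corr$r))

  # constructed sample with exact r(1,2) = 0.8: y = 0.8 x + sqrt(1-0.64) e
  # with e the residual of an orthogonalized vector
  x <- scale(c(-2, -1, 0, 1, 2))
  e <- scale(resid(lm(c(1, -1, 2, 0, -2) ~ x)))
  y <- 0.8 * x + sqrt(1 - 0.64) * e
  d2 <- data.frame(x = as.numeric(x), y = as.numeric(y), z = rnorm(5))
  corr2 <- pairwise_correlations(d2, c("x", "y", "z"))
  expect_equal(corr2$r["x", "y"], 0.8, tolerance = 1e-12)

  expect_error(
    pairwise_correlations(data.frame(a = 1:5, k = rep(1, 5)), c("a", "k")),
    class = "milkcog_error_constant_column"
  )
})

test_that("threshold partitions equal graph components and tree cuts", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.8
  r[1, 3] <- r[3, 1] <- 0.2
  r[2, 3] <- r[3, 2] <- 0.3
  colnames(r) <- rownames(r) <- c("A", "B", "C")
  lab <- single_linkage_clusters(r, 0.5)
  expect_equal(unname(lab), c(1L, 1L, 2L))

  # threshold above the largest off-diagonal correlation: all singletons
  expect_equal(length(unique(single_linkage_clusters(r, 0.9))), 3L)
  expect_error(single_linkage_clusters(r, 1.5), class = "milkcog_error_bad_config")
})

test_that("partitions from union-find, BFS oracle and cutree are identical", {
  same_partition <- function(a, b) {
    # partitions equal up to label renaming
    all(outer(a, a, "==") == outer(b, b, "=="))
  }
  withr::with_seed(42, {
    for (i in 1:60) {
      p <- sample(4:10, 1)
      rm <- random_corr_matrix(p, seed = 1000 + i)
      tc <- runif(1, -0.2, 0.9)
      got <- single_linkage_clusters(rm, tc)
      expect_true(same_partition(got, oracle_components(rm, tc)))
      hc <- merge_tree(rm)
      cut <- cutree(hc, h = 1 - tc)
      expect_true(same_partition(got, cut))
    }
  })
})

test_that("Dunn index matches hand computation and is scale invariant", {
  d <- matrix(0.9, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  diag(d) <- 0
  labels <- c(1, 1, 2, 2)
  expect_equal(dunn_index(d, labels), 9)
  expect_equal(dunn_index(5 * d, labels), 9)

  expect_error(dunn_index(d, rep(1, 4)), class = "milkcog_error_dunn_undefined")
  expect_error(dunn_index(d, 1:4), class = "milkcog_error_dunn_undefined")
  expect_error(dunn_index(d, c(1, 2)), class = "milkcog_error_length_mismatch")
})

test_that("optimal partition matches exhaustive evaluation over all tree cuts", {
  # forced optimum: two well-separated blocks
  blk <- matrix(0.05, 6, 6)
  blk[1:3, 1:3] <- 0.9
  blk[4:6, 4:6] <- 0.9
  diag(blk) <- 1
  colnames(blk) <- rownames(blk) <- paste0("N", 1:6)
  sol <- optimal_partition(blk)
  expect_equal(sol$k, 2L)

  # brute force over cut levels on random instances
  withr::with_seed(7, {
    for (i in 1:25) {
      rm <- random_corr_matrix(10, seed = 2000 + i)
      sol <- optimal_partition(rm)
      d <- 1 - rm
      diag(d) <- 0
      hc <- hclust(as.dist(d), method = "single")
      cuts <- lapply(sort(unique(hc$height)), function(h) cutree(hc, h = h))
      cuts <- c(list(setNames(1:10, colnames(rm))), cuts)
      dunns <- vapply(cuts, function(lab) {
        tryCatch(dunn_index(d, lab), error = function(e) NA_real_)
      }, numeric(1))
      expect_equal(sol$dunn, max(dunns, na.rm = TRUE))
    }
  })
})

test_that("threshold-stability intervals tile the threshold axis", {
  rm <- random_corr_matrix(8, seed = 99)
  sol <- optimal_partition(rm)
  s <- sol$solutions
  # consecutive intervals share endpoints and do not overlap
  expect_equal(s$tc_high[-1], s$tc_low[-nrow(s)])
  expect_true(all(s$tc_low < s$tc_high))
  expect_equal(s$tc_high[1], 1)
  expect_equal(s$tc_low[nrow(s)], -1)
})

test_that("default target reproduces the published 7-cluster structure", {
  sol <- optimal_partition(default_correlation_target())
  expect_equal(sol$k, 7L)
  lab <- sol$selected
  same_group <- function(members) length(unique(lab[members])) == 1
  expect_true(same_group(c("TSFA", "TMUFA", "TPUFA", "ARA")))
  expect_true(same_group(c("DHA", "ARA_DHA")))
  expect_true(same_group(c("PC", "PE", "PI", "SPH")))
  sizes <- table(lab)
  for (nm in c("n6_n3", "Choline", "PCho", "GPC")) {
    expect_equal(unname(sizes[as.character(lab[nm])]), 1L)
  }
  expect_equal(sort(as.integer(sizes)), c(1L, 1L, 1L, 1L, 2L, 4L, 4L))
  # stability interval close to the published 0.53 < Tc <= 0.69
  expect_equal(sol$tc_interval[1], 0.53, tolerance = 0.02)
  expect_equal(sol$tc_interval[2], 0.69, tolerance = 0.02)
})

test_that("MST matches Kruskal oracle and its cut reproduces the partition", {
  # two nutrients: the single edge
  r2 <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  mst2 <- minimum_spanning_tree(r2)
  expect_equal(nrow(mst2), 1L)
  expect_equal(mst2$r, 0.4)

  # 4-node toy, hand-run greedy selection: edges (ab, bc, cd)
  r4 <- diag(4)
  dimnames(r4) <- list(letters[1:4], letters[1:4])
  r4["a", "b"] <- r4["b", "a"] <- 0.9
  r4["b", "c"] <- r4["c", "b"] <- 0.8
  r4["c", "d"] <- r4["d", "c"] <- 0.7
  r4["a", "c"] <- r4["c", "a"] <- 0.3
  r4["a", "d"] <- r4["d", "a"] <- 0.2
  r4["b", "d"] <- r4["d", "b"] <- 0.1
  mst4 <- minimum_spanning_tree(r4)
  key <- function(f, t) paste(pmin(f, t), pmax(f, t))
  expect_setequal(key(mst4$from, mst4$to), c("a b", "b c", "c d"))

  withr::with_seed(11, {
    for (i in 1:30) {
      p <- sample(4:10, 1)
      rm <- random_corr_matrix(p, seed = 3000 + i)
      mst <- minimum_spanning_tree(rm)
      expect_equal(nrow(mst), p - 1)
      # total weight equals Kruskal oracle's (edge sets can differ under ties)
      d <- 1 - rm
      diag(d) <- 0
      ora <- oracle_mst_kruskal(d)
      expect_equal(sum(mst$distance), sum(ora$w), tolerance = 1e-12)
      # acyclic + connected: p-1 edges touching all p nodes in one component
      expect_equal(length(unique(c(mst$from, mst$to))), p)

      # removing MST edges with r < tc reproduces the threshold partition
      tc <- runif(1, 0, 0.9)
      keep <- mst[mst$r >= tc, ]
      lab <- oracle_components_from_edges(colnames(rm), keep)
      got <- single_linkage_clusters(rm, tc)
      expect_true(all(outer(lab, lab, "==") == outer(got, got, "==")))
    }
  })
})

test_that("clustering is invariant to standardization of the inputs", {
  cohort <- simulate_cohort(cohort_config(seed = 5))
  raw <- pairwise_correlations(cohort$baseline)
  std <- pairwise_correlations(
    standardize_columns(cohort$baseline, default_nutrient_panel()$name)
  )
  expect_equal(raw$r, std$r, tolerance = 1e-12)
})
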