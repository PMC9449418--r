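# End-to-end pipeline: simulate/ingest -> scoring -> preprocessing ->
# marginal scans -> clustering -> joint selection -> cross-validation ->
# follow-up prediction, with optional CSV export of every stage.

#' Pipeline configuration
#'
#' @param cohort A `milk_cohort` (from [simulate_cohort()]), a directory
#'   written by [write_cohort()], or `NULL` to simulate with `cohort_config`.
#' @param cohort_config Used when `cohort` is NULL.
#' @param nutrients Nutrient column names.
#' @param confounders Confounder column names.
#' @param fdr_family `"scan"` or `"per_outcome"` for the marginal scan.
#' @param absolute_distance Cluster on `1 - |r|` instead of `1 - r`.
#' @param cv_folds,cv_reps Cross-validation plan.
#' @param followup_bins Tibble `bin_low`/`bin_high` in months.
#' @param min_bin_n Smallest follow-up bin analyzed (smaller bins are skipped
#'   with a log entry, mirroring how under-sampled follow-up windows are
#'   usually dropped).
#' @param use_followup_age Age covariate choice for follow-up prediction.
#' @param loadings IBQ-R factor loadings.
#' @param output_dir Directory for stage CSVs (`NULL`: nothing written).
#' @param seed Integer seed for every stochastic stage of the analysis.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL,
                            cohort_config = milkcog::cohort_config(),
                            nutrients = panel_names()$name,
                            confounders = default_confounders(),
                            fdr_family = c("scan", "per_outcome"),
                            absolute_distance = FALSE,
                            cv_folds = 5, cv_reps = 100,
                            followup_bins = tibble(
                              bin_low = c(6, 9, 12),
                              bin_high = c(9, 12, 18)
                            ),
                            min_bin_n = 10,
                            use_followup_age = FALSE,
                            loadings = default_ibq_loadings(),
                            output_dir = NULL,
                            seed = 1L) {
  fdr_family <- match.arg(fdr_family)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured cohort and, when `output_dir` is
#' set, writes each stage as CSV plus a plain-text run log recording the seed
#' and package version. Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `milk_pipeline`: list with the cohort, stage
#'   results and (if written) output paths.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(cohort = simulate_cohort(cohort_config(seed = 3)), cv_reps = 10)
#' res <- run_pipeline(cfg)
#' names(res)
#' }
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_milkcog(
        sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
        class = "milkcog_error_stage",
        parent = e
      )
    })
  }

  cohort <- stage("ingest", {
    if (is.null(config$cohort)) {
      simulate_cohort(config$cohort_config)
    } else if (is.character(config$cohort)) {
      tables <- read_cohort(config$cohort)
      structure(
        list(
          baseline = tables$baseline, followup = tables$followup,
          config = config$cohort_config
        ),
        class = "milk_cohort"
      )
    } else {
      stopifnot(inherits(config$cohort, "milk_cohort"))
      config$cohort
    }
  })

  stage("validate", {
    assert_columns(
      cohort$baseline,
      c(
        "subject_id", config$confounders, config$nutrients,
        msel_cols(), ibq_cols()
      ),
      where = "baseline cohort"
    )
  })

  characteristics <- stage("describe", cohort_characteristics(cohort))
  nutrient_summary <- stage("describe", summarize_nutrients(cohort$baseline, config$nutrients))
  age_trends <- stage("describe", nutrient_age_trends(cohort$baseline, config$nutrients))

  frames <- stage("preprocess", list(
    msel = build_analysis_frame(cohort$baseline, "msel", config$nutrients, config$loadings),
    ibq = build_analysis_frame(cohort$baseline, "ibq", config$nutrients, config$loadings)
  ))
  subset_comparison <- stage("describe", compare_cohort_subsets(
    cohort$baseline, frames$msel$subject_id, frames$ibq$subject_id, config$nutrients
  ))

  marginal <- stage("marginal", lapply(frames, function(fr) {
    marginal_scan(fr,
      nutrients = config$nutrients, confounders = config$confounders,
      family = config$fdr_family
    )
  }))

  correlations <- stage(
    "cluster",
    pairwise_correlations(cohort$baseline, config$nutrients)
  )
  partition <- stage("cluster", optimal_partition(correlations, config$absolute_distance))
  mst <- stage("cluster", minimum_spanning_tree(correlations, config$absolute_distance))

  fits <- stage("select", lapply(frames, function(fr) {
    joint_selection_scan(fr, partition$selected, confounders = config$confounders)
  }))

  cv <- stage("validate_cv", {
    out <- list()
    i <- 0L
    for (instr in names(fits)) {
      for (oc in names(fits[[instr]])) {
        i <- i + 1L
        fit <- fits[[instr]][[oc]]
        if (fit$q == 0) next
        out[[oc]] <- repeated_cv(
          frames[[instr]], oc, fit$selected,
          confounders = config$confounders,
          folds = config$cv_folds, reps = config$cv_reps,
          seed = (config$seed + i) %% .Machine$integer.max
        )
      }
    }
    out
  })

  followup <- stage("followup", run_followup(cohort, frames, fits, config))

  result <- structure(
    list(
      cohort = cohort, characteristics = characteristics,
      nutrient_summary = nutrient_summary, age_trends = age_trends,
      subset_comparison = subset_comparison,
      frames = frames, marginal = marginal,
      correlations = correlations, partition = partition, mst = mst,
      fits = fits, cv = cv, followup = followup,
      config = config, paths = NULL
    ),
    class = "milk_pipeline"
  )
  if (!is.null(config$output_dir)) {
    result$paths <- stage("export", export_pipeline(result, config$output_dir))
  }
  result
}

summarize_nutrients <- function(baseline, nutrients) {
  purrr::map_dfr(nutrients, function(nm) {
    x <- baseline[[nm]]
    tibble(
      nutrient = nm, mean = mean(x), sd = stats::sd(x),
      median = stats::median(x),
      q05 = unname(stats::quantile(x, 0.05)),
      q95 = unname(stats::quantile(x, 0.95))
    )
  })
}

run_followup <- function(cohort, frames, fits, config) {
  fu <- cohort$followup
  if (is.null(fu) || nrow(fu) == 0) {
    return(list())
  }
  out <- list()
  for (instr in names(fits)) {
    rows <- fu[fu$instrument == instr, , drop = FALSE]
    if (nrow(rows) == 0) next
    rows <- if (instr == "msel") {
      add_elc(rows)
    } else {
      add_ibq_factors(rows, config$loadings)
    }
    # keep bins with enough follow-up observations
    counts <- vapply(seq_len(nrow(config$followup_bins)), function(b) {
      sum(rows$visit_age_months > config$followup_bins$bin_low[b] &
        rows$visit_age_months <= config$followup_bins$bin_high[b])
    }, numeric(1))
    bins <- config$followup_bins[counts >= config$min_bin_n, , drop = FALSE]
    if (nrow(bins) == 0) next
    for (oc in names(fits[[instr]])) {
      fit <- fits[[instr]][[oc]]
      if (!oc %in% names(rows)) next
      out[[oc]] <- followup_predict(
        fit, frames[[instr]], rows,
        observed = oc, bins = bins,
        use_followup_age = config$use_followup_age
      )
    }
  }
  out
}

export_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    paths[name] <<- path
  }
  put(result$characteristics, "table1_characteristics")
  put(result$nutrient_summary, "table2_nutrient_summary")
  put(result$age_trends, "nutrient_age_trends")
  put(result$subset_comparison, "subset_comparison")
  put(marginal_table(result$marginal$msel), "table3_marginal_msel")
  put(marginal_table(result$marginal$ibq), "table4_marginal_ibq")
  put(
    dplyr::bind_rows(lapply(result$marginal, as_tibble), .id = "instrument"),
    "marginal_long"
  )
  corr <- result$correlations$r
  put(cbind(nutrient = rownames(corr), as.data.frame(corr)), "correlation_matrix")
  put(result$mst, "minimum_spanning_tree")
  put(tidy(result$partition), "table5_partitions")
  for (instr in names(result$fits)) {
    put(joint_table(result$fits[[instr]]), paste0("table6_joint_", instr))
  }
  if (length(result$cv) > 0) {
    put(
      dplyr::bind_rows(lapply(result$cv, glance)),
      "cv_summary"
    )
    put(
      dplyr::bind_rows(lapply(result$cv, tidy), .id = "outcome"),
      "cv_repetitions"
    )
  }
  if (length(result$followup) > 0) {
    put(
      dplyr::bind_rows(
        lapply(result$followup, function(f) {
          dplyr::select(as_tibble(f), -"predictions")
        }),
        .id = "outcome"
      ),
      "followup_correlations"
    )
    put(
      dplyr::bind_rows(
        lapply(result$followup, function(f) {
          tidyr::unnest(
            dplyr::select(as_tibble(f), "bin", "predictions"), "predictions"
          )
        }),
        .id = "outcome"
      ),
      "followup_predictions"
    )
  }
  log_path <- file.path(dir, "run_log.txt")
  writeLines(c(
    sprintf("milkcog version: %s", as.character(utils::packageVersion("milkcog"))),
    sprintf("seed: %d", result$config$seed),
    sprintf("fdr_family: %s", result$config$fdr_family),
    sprintf("cv: %d repetitions of %d-fold", result$config$cv_reps, result$config$cv_folds),
    sprintf("selected clusters: k = %d (Dunn %.4f)", result$partition$k, result$partition$dunn),
    "note: joint-model F-tests are post-selection and anti-conservative"
  ), log_path)
  paths["run_log"] <- log_path
  paths
}

#' @export
print.milk_pipeline <- function(x, ...) {
  cat("<milk_pipeline>\n")
  cat(
    "  cohort:", nrow(x$cohort$baseline), "subjects;",
    nrow(x$frames$msel), "MSEL,", nrow(x$frames$ibq), "IBQ-R\n"
  )
  cat(
    "  clustering: k =", x$partition$k,
    sprintf("(Dunn %.3f)", x$partition$dunn), "\n"
  )
  for (instr in names(x$fits)) {
    for (oc in names(x$fits[[instr]])) {
      f <- x$fits[[instr]][[oc]]
      cat(sprintf(
        "  %s: R2 %.2f adj %.2f p_adj %.3g [%s]\n",
        oc, f$r2, f$adj_r2, f$p_adj,
        if (f$q == 0) "none" else paste(f$selected, collapse = ", ")
      ))
    }
  }
  invisible(x)
}
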