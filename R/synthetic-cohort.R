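# Synthetic cohort generator.
#
# Generates cohorts with the statistical structure the downstream analysis
# assumes: nutrient concentrations drawn multivariate-normal on the
# standardized scale with a block correlation target, affinely mapped to the
# published means/SDs and clamped at zero; outcome scores generated from
# linear models on standardized predictors with Gaussian noise; instrument
# availability, missing-income and follow-up visit patterns matching the
# study design.

#' Sample a nutrient concentration table
#'
#' Draws `n` subjects from a multivariate normal on the standardized scale
#' with the given correlation target, maps each column to its panel mean/SD
#' and clamps negative concentrations to zero. The fraction of clamped values
#' per nutrient is attached as attribute `truncation_fraction`; for nutrients
#' whose mean is less than about 2.33 SDs above zero (DHA, free choline in the
#' default panel) this fraction necessarily exceeds 1% under normality.
#'
#' @param n Number of subjects (rows).
#' @param panel Nutrient specification tibble with columns `name`, `mean`,
#'   `sd`; see [default_nutrient_panel()].
#' @param target Correlation matrix whose dimnames match `panel$name`.
#'   Non-PSD targets are repaired with [repair_correlation_matrix()].
#' @param seed Optional integer seed; the draw is reproducible given the seed.
#' @return A tibble with `n` rows and one column per nutrient.
#' @export
#' @examples
#' x <- sample_nutrient_matrix(54, seed = 1)
#' dim(x)
sample_nutrient_matrix <- function(n,
                                   panel = default_nutrient_panel(),
                                   target = default_correlation_target(),
                                   seed = NULL) {
  if (n < 1) stop_milkcog("n must be at least 1", class = "milkcog_error_bad_config")
  if (any(panel$sd <= 0)) {
    stop_milkcog("all panel SDs must be positive", class = "milkcog_error_bad_config")
  }
  if (anyDuplicated(panel$name)) {
    stop_milkcog("panel nutrient names must be unique", class = "milkcog_error_bad_config")
  }
  if (is.null(dimnames(target)) ||
    !identical(sort(colnames(target)), sort(panel$name))) {
    stop_milkcog("correlation target labels must match the panel nutrient names",
      class = "milkcog_error_bad_target"
    )
  }
  target <- target[panel$name, panel$name]
  target <- repair_correlation_matrix(target)

  draw <- function() {
    p <- nrow(panel)
    lchol <- tryCatch(chol(target), error = function(e) NULL)
    z <- matrix(stats::rnorm(n * p), nrow = n)
    if (is.null(lchol)) {
      # rank-deficient PSD target: eigen square root
      ev <- eigen(target, symmetric = TRUE)
      z <- z %*% (t(ev$vectors) * sqrt(pmax(ev$values, 0)))
    } else {
      z <- z %*% lchol
    }
    x <- sweep(sweep(z, 2, panel$sd, `*`), 2, panel$mean, `+`)
    colnames(x) <- panel$name
    truncated <- colMeans(x < 0)
    x[x < 0] <- 0
    out <- as_tibble(as.data.frame(x))
    attr(out, "truncation_fraction") <- truncated
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Specify a linear outcome-generating model
#'
#' Outcomes are generated as `intercept + sum(beta_j * z_j) + noise`, where
#' the `z_j` are the z-scored predictor columns named by `coefficients`. When
#' `target_r2` is supplied the residual SD is derived so that the model
#' explains that fraction of the outcome variance (computed against the
#' realized variance of the linear predictor); `noise_sd` is then ignored.
#'
#' @param outcome_name Label for the generated outcome.
#' @param coefficients Named numeric vector of standardized effects.
#' @param intercept Intercept on the outcome scale (default 0).
#' @param noise_sd Residual standard deviation (default 1); must be >= 0.
#' @param target_r2 Optional fraction in (0, 1); when given, `noise_sd` is
#'   derived, not set.
#' @return An object of class `outcome_model_spec`.
#' @export
#' @examples
#' outcome_model_spec("sur", c(ARA = 0.42, PI = 0.19, PCho = 0.27), target_r2 = 0.43)
outcome_model_spec <- function(outcome_name, coefficients = numeric(),
                               intercept = 0, noise_sd = 1, target_r2 = NULL) {
  if (length(coefficients) > 0 && is.null(names(coefficients))) {
    stop_milkcog("coefficients must be a named vector", class = "milkcog_error_bad_config")
  }
  if (is.null(target_r2)) {
    if (noise_sd < 0) {
      stop_milkcog("noise_sd must be >= 0", class = "milkcog_error_bad_config")
    }
  } else {
    if (target_r2 <= 0 || target_r2 >= 1) {
      stop_milkcog("target_r2 must lie in (0, 1)", class = "milkcog_error_bad_config")
    }
    noise_sd <- NA_real_
  }
  structure(
    list(
      outcome_name = outcome_name, coefficients = coefficients,
      intercept = intercept, noise_sd = noise_sd, target_r2 = target_r2
    ),
    class = "outcome_model_spec"
  )
}

#' Generate an outcome column from predictors
#'
#' @param data Data frame containing every column named in the model's
#'   coefficients.
#' @param spec An [outcome_model_spec()].
#' @param seed Optional integer seed for the residual draw.
#' @return Numeric vector of length `nrow(data)` with attribute `noise_sd`
#'   (the residual SD actually used).
#' @export
sample_outcomes <- function(data, spec, seed = NULL) {
  stopifnot(inherits(spec, "outcome_model_spec"))
  beta <- spec$coefficients[spec$coefficients != 0]
  assert_columns(data, names(beta), where = "outcome model predictors")
  n <- nrow(data)
  lp <- rep(0, n)
  for (nm in names(beta)) {
    lp <- lp + beta[[nm]] * zscore(data[[nm]], label = nm)
  }
  noise_sd <- spec$noise_sd
  if (!is.null(spec$target_r2)) {
    v <- stats::var(lp) * (n - 1) / n
    if (v == 0) {
      stop_milkcog("target_r2 requires at least one nonzero coefficient",
        class = "milkcog_error_bad_config"
      )
    }
    noise_sd <- sqrt(v * (1 - spec$target_r2) / spec$target_r2)
  }
  draw <- function() spec$intercept + lp +
    if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  y <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  attr(y, "noise_sd") <- noise_sd
  y
}

#' Default outcome-generating models
#'
#' The published multiple-regression coefficient rows for the gross-motor and
#' receptive-language MSEL subscales and the surgency and regulation IBQ-R
#' factors, with residual noise calibrated to the corresponding published R²
#' (0.42, 0.36, 0.43, 0.23). Subscales/factors for which no model was
#' published (visual reception, fine motor, expressive language, negative
#' affectivity) are pure-noise nulls.
#'
#' @return Named list with elements `msel` (specs `gm`, `vr`, `fm`, `rl`,
#'   `el`) and `ibq` (specs `sur`, `neg`, `reg`).
#' @export
default_outcome_models <- function() {
  list(
    msel = list(
      gm = outcome_model_spec(
        "gross_motor",
        c(TMUFA = -0.51, n6_n3 = 0.19, DHA = 0.30, SPH = -0.24),
        target_r2 = 0.42
      ),
      vr = outcome_model_spec("visual_reception"),
      fm = outcome_model_spec("fine_motor"),
      rl = outcome_model_spec(
        "receptive_language",
        c(TSFA = -0.30, n6_n3 = 0.37, DHA = 0.75, PE = 0.30),
        target_r2 = 0.36
      ),
      el = outcome_model_spec("expressive_language")
    ),
    ibq = list(
      sur = outcome_model_spec(
        "surgency",
        c(ARA = 0.42, PI = 0.19, PCho = 0.27),
        target_r2 = 0.43
      ),
      neg = outcome_model_spec("negative_affectivity"),
      reg = outcome_model_spec(
        "regulation",
        c(ARA = 0.39),
        target_r2 = 0.23
      )
    )
  )
}

#' Cohort simulation configuration
#'
#' Defaults reproduce the study design: 54 subjects under 6 months, MSEL
#' available for 38, IBQ-R for 42, both for 26; two missing household-income
#' values; visit age 4.43 +/- 0.83 months; 19/54 male; follow-up MSEL visits
#' of 27/34/25 subjects in the (6,9], (9,12] and (12,18] month bins and 27
#' IBQ-R follow-ups at (12,18] months.
#'
#' @param n_subjects,n_msel,n_ibq,n_both Cohort and instrument subset sizes.
#' @param missing_income Number of income values set missing completely at
#'   random.
#' @param age_mean,age_sd,age_min,age_max Baseline visit age distribution
#'   (months), clamped into `[age_min, age_max]`.
#' @param sex_p,site_p,income_p Bernoulli rates for male sex, site indicator
#'   and household income below 75k.
#' @param panel,target Nutrient panel and correlation target.
#' @param outcome_models See [default_outcome_models()].
#' @param msel_t_mean,msel_t_sd Affine map from the standardized outcome scale
#'   to MSEL T-scores.
#' @param ibq_mean,ibq_scale,ibq_subscale_noise_sd IBQ-R subscale construction:
#'   `subscale = ibq_mean + ibq_scale * factor + noise`.
#' @param followup_msel,followup_ibq Tibbles with one row per age bin:
#'   `bin_low`, `bin_high`, `n`, `age_mean`, `age_sd`.
#' @param followup_noise_scale Multiplier on the generating residual SD at
#'   follow-up visits.
#' @param seed Integer seed controlling all randomness.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 54, n_msel = 38, n_ibq = 42, n_both = 26,
                          missing_income = 2,
                          age_mean = 4.43, age_sd = 0.83,
                          age_min = 0.5, age_max = 6,
                          sex_p = 19 / 54, site_p = 0.5, income_p = 18 / 52,
                          panel = default_nutrient_panel(),
                          target = default_correlation_target(),
                          outcome_models = default_outcome_models(),
                          msel_t_mean = 50, msel_t_sd = 10,
                          ibq_mean = 4, ibq_scale = 0.8,
                          ibq_subscale_noise_sd = 0.5,
                          followup_msel = tibble(
                            bin_low = c(6, 9, 12), bin_high = c(9, 12, 18),
                            n = c(27, 34, 25),
                            age_mean = c(7.63, 10.5, 14.02),
                            age_sd = c(0.87, 0.97, 1.08)
                          ),
                          followup_ibq = tibble(
                            bin_low = 12, bin_high = 18, n = 27,
                            age_mean = 13.34, age_sd = 0.79
                          ),
                          followup_noise_scale = 1,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (n_both > min(n_msel, n_ibq)) {
    stop_milkcog("n_both cannot exceed either instrument subset size",
      class = "milkcog_error_bad_config"
    )
  }
  if (n_msel + n_ibq - n_both > n_subjects) {
    stop_milkcog("instrument subset sizes exceed the number of subjects",
      class = "milkcog_error_bad_config"
    )
  }
  if (missing_income > n_subjects) {
    stop_milkcog("more missing income values than subjects",
      class = "milkcog_error_bad_config"
    )
  }
  for (fu in list(followup_msel, followup_ibq)) {
    n_instr <- if (identical(fu, followup_msel)) n_msel else n_ibq
    if (nrow(fu) > 0 && any(fu$n > n_instr)) {
      stop_milkcog("a follow-up bin requests more subjects than have the instrument",
        class = "milkcog_error_bad_config"
      )
    }
  }
  structure(cfg, class = "cohort_config")
}

ibq_cols <- function() sprintf("ibq_%02d", 1:14)
msel_cols <- function() paste0("msel_", c("gm", "vr", "fm", "rl", "el"))

#' Simulate a cohort
#'
#' Generates the baseline subject-visit table (nutrients, confounders, MSEL
#' subscale T-scores where available, IBQ-R subscale means where available)
#' and the follow-up visit table, fully reproducibly given the config seed.
#'
#' @param config A [cohort_config()].
#' @return An object of class `milk_cohort`: list with tibbles `baseline` and
#'   `followup` plus the `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 7))
#' nrow(cohort$baseline)
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects
  nutrients <- sample_nutrient_matrix(n, cfg$panel, cfg$target)
  baseline <- tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    visit_age_months = pmin(pmax(stats::rnorm(n, cfg$age_mean, cfg$age_sd), cfg$age_min), cfg$age_max),
    sex = stats::rbinom(n, 1, cfg$sex_p),
    site = stats::rbinom(n, 1, cfg$site_p),
    income_lt75k = as.numeric(stats::rbinom(n, 1, cfg$income_p))
  )
  if (cfg$missing_income > 0) {
    baseline$income_lt75k[sample.int(n, cfg$missing_income)] <- NA_real_
  }
  baseline <- dplyr::bind_cols(baseline, nutrients)

  # instrument availability: stratified random assignment matching the counts
  ids <- sample(baseline$subject_id)
  both_ids <- ids[seq_len(cfg$n_both)]
  msel_only <- ids[cfg$n_both + seq_len(cfg$n_msel - cfg$n_both)]
  ibq_only <- ids[cfg$n_msel + seq_len(cfg$n_ibq - cfg$n_both)]
  has_msel <- baseline$subject_id %in% c(both_ids, msel_only)
  has_ibq <- baseline$subject_id %in% c(both_ids, ibq_only)

  # MSEL subscales on the T-score scale
  for (sub in names(cfg$outcome_models$msel)) {
    z <- sample_outcomes(baseline, cfg$outcome_models$msel[[sub]])
    col <- paste0("msel_", sub)
    baseline[[col]] <- cfg$msel_t_mean + cfg$msel_t_sd * as.numeric(z)
    baseline[[col]][!has_msel] <- NA_real_
  }

  # IBQ-R: latent factors, then subscales = location + scale * factor + noise
  factors <- vapply(
    cfg$outcome_models$ibq,
    function(spec) as.numeric(sample_outcomes(baseline, spec)),
    numeric(n)
  )
  loadings <- default_ibq_loadings()
  factor_of <- apply(loadings[, c("SUR", "NEG", "REG")], 1, function(w) {
    c("sur", "neg", "reg")[which.max(w)]
  })
  for (i in seq_along(ibq_cols())) {
    col <- ibq_cols()[i]
    baseline[[col]] <- cfg$ibq_mean + cfg$ibq_scale * factors[, factor_of[i]] +
      stats::rnorm(n, 0, cfg$ibq_subscale_noise_sd)
    baseline[[col]][!has_ibq] <- NA_real_
  }

  followup <- dplyr::bind_rows(
    simulate_followup(cfg, baseline, "msel", cfg$followup_msel,
      subjects = baseline$subject_id[has_msel]
    ),
    simulate_followup(cfg, baseline, "ibq", cfg$followup_ibq,
      subjects = baseline$subject_id[has_ibq]
    )
  )
  structure(
    list(baseline = baseline, followup = followup, config = cfg),
    class = "milk_cohort"
  )
}

# Follow-up scores reuse the baseline generating models (same nutrient values,
# fresh residuals scaled by followup_noise_scale).
simulate_followup <- function(cfg, baseline, instrument, bins, subjects) {
  if (is.null(bins) || nrow(bins) == 0) {
    return(tibble())
  }
  out <- vector("list", nrow(bins))
  for (b in seq_len(nrow(bins))) {
    ids <- sample(subjects, bins$n[b])
    rows <- baseline[match(ids, baseline$subject_id), ]
    eps <- 1e-6
    age <- pmin(
      pmax(stats::rnorm(bins$n[b], bins$age_mean[b], bins$age_sd[b]), bins$bin_low[b] + eps),
      bins$bin_high[b]
    )
    rec <- tibble(
      subject_id = ids, instrument = instrument,
      bin = sprintf("(%g,%g]", bins$bin_low[b], bins$bin_high[b]),
      visit_age_months = age
    )
    if (instrument == "msel") {
      for (sub in names(cfg$outcome_models$msel)) {
        spec <- cfg$outcome_models$msel[[sub]]
        y <- sample_outcomes(rows, rescale_noise(spec, rows, cfg$followup_noise_scale))
        rec[[paste0("msel_", sub)]] <- cfg$msel_t_mean + cfg$msel_t_sd * as.numeric(y)
      }
    } else {
      factors <- vapply(
        cfg$outcome_models$ibq,
        function(spec) {
          as.numeric(sample_outcomes(rows, rescale_noise(spec, rows, cfg$followup_noise_scale)))
        },
        numeric(nrow(rows))
      )
      loadings <- default_ibq_loadings()
      factor_of <- apply(loadings[, c("SUR", "NEG", "REG")], 1, function(w) {
        c("sur", "neg", "reg")[which.max(w)]
      })
      for (i in seq_along(ibq_cols())) {
        rec[[ibq_cols()[i]]] <- cfg$ibq_mean +
          cfg$ibq_scale * factors[, factor_of[i]] +
          stats::rnorm(nrow(rows), 0, cfg$ibq_subscale_noise_sd)
      }
    }
    out[[b]] <- rec
  }
  dplyr::bind_rows(out)
}

# Resolve a target_r2 spec into an explicit noise_sd on the given rows, then
# scale it; keeps follow-up noise comparable to baseline noise.
rescale_noise <- function(spec, rows, scale) {
  if (!is.null(spec$target_r2)) {
    y <- sample_outcomes(rows, spec, seed = 0L)
    spec$noise_sd <- attr(y, "noise_sd")
    spec$target_r2 <- NULL
  }
  spec$noise_sd <- spec$noise_sd * scale
  spec
}

#' @export
print.milk_cohort <- function(x, ...) {
  cat(
    "<milk_cohort>", nrow(x$baseline), "baseline subjects,",
    nrow(x$followup), "follow-up records (seed", x$config$seed, ")\n"
  )
  invisible(x)
}

#' Write / read a cohort as CSV
#'
#' The baseline and follow-up tables are written as plain CSV with the
#' published nutrient column names (`n-6/n-3`, `ARA/DHA`, ...); a sidecar
#' plain-text file records the scalar generation parameters and the seed.
#'
#' @param cohort A `milk_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` invisibly returns the file paths; `read_cohort`
#'   returns a list with `baseline` and `followup` tibbles using the internal
#'   (syntactic) nutrient names.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "milk_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  map <- panel_names()
  rename_out <- function(df) {
    names(df)[match(map$name, names(df))] <- map$display
    df
  }
  paths <- c(
    baseline = file.path(dir, "cohort_baseline.csv"),
    followup = file.path(dir, "cohort_followup.csv"),
    config = file.path(dir, "cohort_config.txt")
  )
  utils::write.csv(rename_out(cohort$baseline), paths["baseline"], row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$followup), paths["followup"], row.names = FALSE)
  cfg <- cohort$config
  scalars <- Filter(function(v) is.atomic(v) && length(v) == 1, unclass(cfg))
  lines <- c(
    sprintf("%s: %s", names(scalars), vapply(scalars, format, character(1))),
    outcome_model_lines(cfg$outcome_models)
  )
  writeLines(lines, paths["config"])
  invisible(paths)
}

outcome_model_lines <- function(models) {
  unlist(lapply(names(models), function(instr) {
    unlist(lapply(names(models[[instr]]), function(sub) {
      spec <- models[[instr]][[sub]]
      coefs <- if (length(spec$coefficients) == 0) {
        "(none)"
      } else {
        paste(sprintf("%s=%g", names(spec$coefficients), spec$coefficients),
          collapse = ", "
        )
      }
      sprintf(
        "model.%s.%s: coefficients %s; intercept %g; %s", instr, sub, coefs,
        spec$intercept,
        if (is.null(spec$target_r2)) {
          sprintf("noise_sd %g", spec$noise_sd)
        } else {
          sprintf("target_r2 %g", spec$target_r2)
        }
      )
    }))
  }))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  map <- panel_names()
  rename_in <- function(df) {
    names(df)[match(map$display, names(df))] <- map$name
    as_tibble(df)
  }
  baseline <- utils::read.csv(file.path(dir, "cohort_baseline.csv"),
    check.names = FALSE
  )
  followup_path <- file.path(dir, "cohort_followup.csv")
  followup <- if (file.exists(followup_path)) {
    as_tibble(utils::read.csv(followup_path, check.names = FALSE))
  } else {
    tibble()
  }
  list(baseline = rename_in(baseline), followup = followup)
}
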