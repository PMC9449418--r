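# Default nutrient panel and correlation target.
#
# The panel covers three nutrient families measured in mature human milk:
# fatty acids (TSFA, TMUFA, TPUFA in g/100ml; ARA, DHA in mg/100ml; the
# dimensionless ratios ARA/DHA and n-6/n-3), phospholipids (PC, PE, PI, SPH in
# mg/100ml) and choline metabolites (free choline, PCho, GPC in mcmol/l).

# Internal (syntactic) names, their published display names and units.
panel_names <- function() {
  tibble::tribble(
    ~name,      ~display,   ~unit,
    "TSFA",     "TSFA",     "g/100ml",
    "TMUFA",    "TMUFA",    "g/100ml",
    "TPUFA",    "TPUFA",    "g/100ml",
    "n6_n3",    "n-6/n-3",  "ratio",
    "ARA",      "ARA",      "mg/100ml",
    "DHA",      "DHA",      "mg/100ml",
    "ARA_DHA",  "ARA/DHA",  "ratio",
    "PC",       "PC",       "mg/100ml",
    "PE",       "PE",       "mg/100ml",
    "PI",       "PI",       "mg/100ml",
    "SPH",      "SPH",      "mg/100ml",
    "Choline",  "Choline",  "mcmol/l",
    "PCho",     "PCho",     "mcmol/l",
    "GPC",      "GPC",      "mcmol/l"
  )
}

#' Default 14-nutrient panel
#'
#' Means and standard deviations of the milk nutrient concentrations observed
#' in the first six postpartum months (fatty acids in g/100ml or mg/100ml,
#' phospholipids in mg/100ml, choline metabolites in mcmol/l, ratios
#' dimensionless), together with the correlation-cluster membership each
#' nutrient ends up in at the Dunn-optimal partition.
#'
#' @return A tibble with one row per nutrient: `name` (syntactic column name),
#'   `display` (published label), `unit`, `mean`, `sd`, `cluster_id`.
#' @export
#' @examples
#' default_nutrient_panel()
default_nutrient_panel <- function() {
  out <- panel_names()
  stats <- tibble::tribble(
    ~name,      ~mean,   ~sd,
    "TSFA",      1.54,   0.59,
    "TMUFA",     1.32,   0.53,
    "TPUFA",     0.64,   0.26,
    "n6_n3",    10.57,   2.27,
    "ARA",      20.07,   6.32,
    "DHA",       8.35,   5.14,
    "ARA_DHA",   3.24,   1.73,
    "PC",        4.99,   2.58,
    "PE",        7.53,   3.98,
    "PI",        3.06,   1.19,
    "SPH",       7.70,   3.61,
    "Choline", 216.49, 140.47,
    "PCho",    448.85, 235.64,
    "GPC",     568.53, 192.07
  )
  clusters <- c(
    TSFA = 1L, TMUFA = 1L, TPUFA = 1L, ARA = 1L,
    n6_n3 = 2L, DHA = 3L, ARA_DHA = 3L,
    PC = 4L, PE = 4L, PI = 4L, SPH = 4L,
    Choline = 5L, PCho = 6L, GPC = 7L
  )
  out <- dplyr::left_join(out, stats, by = "name")
  out$cluster_id <- unname(clusters[out$name])
  out
}

#' Nearest positive semi-definite repair of a correlation matrix
#'
#' Clips negative eigenvalues to a small positive floor and rescales to unit
#' diagonal. Refuses repairs that move the matrix by more than `max_frobenius`
#' (a badly mis-specified target should be fixed by the user, not silently
#' rewritten).
#'
#' @param mat Symmetric matrix with unit diagonal and entries in \[-1, 1\].
#' @param max_frobenius Largest allowed Frobenius distance between input and
#'   repaired matrix (default 0.05).
#' @return A positive semi-definite correlation matrix with the same dimnames.
#' @export
repair_correlation_matrix <- function(mat, max_frobenius = 0.05) {
  validate_correlation_target(mat, require_psd = FALSE)
  ev <- eigen(mat, symmetric = TRUE)
  if (min(ev$values) >= 0) {
    return(mat)
  }
  v <- pmax(ev$values, 1e-8)
  repaired <- ev$vectors %*% (v * t(ev$vectors))
  d <- sqrt(diag(repaired))
  repaired <- repaired / tcrossprod(d)
  diag(repaired) <- 1
  dimnames(repaired) <- dimnames(mat)
  dist <- norm(mat - repaired, type = "F")
  if (dist > max_frobenius) {
    stop_milkcog(
      sprintf(
        "correlation target is not positive semi-definite and the nearest PSD matrix is %.3f away (Frobenius), beyond the allowed %.3f",
        dist, max_frobenius
      ),
      class = "milkcog_error_not_psd"
    )
  }
  attr(repaired, "repair_frobenius") <- dist
  repaired
}

validate_correlation_target <- function(mat, require_psd = TRUE) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) {
    stop_milkcog("correlation target must be a square matrix",
      class = "milkcog_error_bad_target"
    )
  }
  if (max(abs(mat - t(mat))) > 1e-8) {
    stop_milkcog("correlation target must be symmetric",
      class = "milkcog_error_bad_target"
    )
  }
  if (max(abs(diag(mat) - 1)) > 1e-8) {
    stop_milkcog("correlation target must have unit diagonal",
      class = "milkcog_error_bad_target"
    )
  }
  if (max(abs(mat)) > 1 + 1e-8) {
    stop_milkcog("correlation entries must lie in [-1, 1]",
      class = "milkcog_error_bad_target"
    )
  }
  if (require_psd && min(eigen(mat, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop_milkcog("correlation target is not positive semi-definite",
      class = "milkcog_error_not_psd"
    )
  }
  invisible(TRUE)
}

#' Default nutrient correlation target
#'
#' Pairwise Pearson correlation targets for the 14-nutrient panel. The block
#' structure encodes what is known about the panel: a tightly linked
#' fatty-acid chain (TSFA-TMUFA-TPUFA-ARA), the DHA and ARA/DHA pair, a
#' phospholipid block (PC, PE, PI, SPH), moderate links among the choline
#' metabolites (PCho-Choline 0.50, GPC joining the phospholipids at 0.53), the
#' strongest cross-family link TSFA-PC at 0.28, and weak family-level
#' background correlations elsewhere. Under single-linkage clustering of
#' `1 - r` this matrix yields a Dunn-optimal 7-cluster partition stable for
#' thresholds between roughly 0.53 and 0.69, with PI splitting off above 0.69
#' and PC above 0.74.
#'
#' The hand-specified blocks are not exactly positive semi-definite; the
#' returned matrix is the eigenvalue-clipped nearest PSD repair (Frobenius
#' distance about 0.034).
#'
#' @return A 14 x 14 positive semi-definite correlation matrix with nutrient
#'   names as dimnames.
#' @export
#' @examples
#' r <- default_correlation_target()
#' r["TSFA", "PC"]
default_correlation_target <- function() {
  labs <- panel_names()$name
  fam <- c(
    TSFA = "fa", TMUFA = "fa", TPUFA = "fa", n6_n3 = "ratio", ARA = "fa",
    DHA = "dha", ARA_DHA = "dha", PC = "pl", PE = "pl", PI = "pl", SPH = "pl",
    Choline = "chol", PCho = "chol", GPC = "chol"
  )
  background <- matrix(0.10, 5, 5,
    dimnames = list(
      c("fa", "ratio", "dha", "pl", "chol"),
      c("fa", "ratio", "dha", "pl", "chol")
    )
  )
  background["fa", "pl"] <- background["pl", "fa"] <- 0.18
  background["fa", "ratio"] <- background["ratio", "fa"] <- 0.30
  background["ratio", "dha"] <- background["dha", "ratio"] <- 0.35
  background["pl", "chol"] <- background["chol", "pl"] <- 0.20
  background["fa", "dha"] <- background["dha", "fa"] <- 0.15

  r <- diag(14)
  dimnames(r) <- list(labs, labs)
  for (i in seq_len(13)) {
    for (j in seq(i + 1, 14)) {
      r[i, j] <- r[j, i] <- background[fam[labs[i]], fam[labs[j]]]
    }
  }
  set_r <- function(a, b, v) {
    r[a, b] <<- v
    r[b, a] <<- v
  }
  # fatty-acid chain keeps the block connected up to threshold ~0.77
  set_r("TSFA", "TMUFA", 0.80)
  set_r("TMUFA", "TPUFA", 0.79)
  set_r("TPUFA", "ARA", 0.77)
  set_r("TSFA", "TPUFA", 0.68)
  set_r("TSFA", "ARA", 0.60)
  set_r("TMUFA", "ARA", 0.66)
  set_r("DHA", "ARA_DHA", 0.78)
  # phospholipid block: PI is the weakest member (splits above 0.69),
  # PC next (splits above 0.74)
  set_r("PE", "SPH", 0.80)
  set_r("PC", "PE", 0.74)
  set_r("PC", "SPH", 0.64)
  set_r("PE", "PI", 0.69)
  set_r("PC", "PI", 0.60)
  set_r("SPH", "PI", 0.61)
  set_r("Choline", "PCho", 0.50)
  set_r("Choline", "GPC", 0.38)
  set_r("PCho", "GPC", 0.32)
  # GPC is the first cross-family merge (into the phospholipids at 0.53)
  set_r("GPC", "PC", 0.53)
  set_r("GPC", "PE", 0.35)
  set_r("GPC", "SPH", 0.33)
  set_r("GPC", "PI", 0.30)
  set_r("TSFA", "PC", 0.28)
  set_r("n6_n3", "ARA", 0.40)
  set_r("n6_n3", "ARA_DHA", 0.45)
  set_r("n6_n3", "DHA", -0.20)
  repair_correlation_matrix(r)
}
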