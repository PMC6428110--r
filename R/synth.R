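# Synthetic cohort generator: plants known age-varying correlation
# structure (Gaussian copula with linear-in-age correlation entries) so
# every downstream stage can be validated against ground truth.

#' Configuration for the synthetic cohort generator
#'
#' Describes a cross-sectional cohort whose biomarker correlation matrix
#' drifts linearly with age. Pairwise target correlations at age `a` are
#' `clip(intercept + slope * (a - 20))` on the planted pairs and
#' `background_correlation` elsewhere, clipped to [-0.95, 0.95] and
#' projected to the nearest positive-semidefinite correlation matrix per
#' integer age.
#'
#' @param n_participants number of participants.
#' @param n_biomarkers number of biomarker columns.
#' @param age_range integer vector `c(lo, hi)`; ages are drawn uniformly on
#'   the integers `lo, ..., hi - 1`. Must satisfy `20 <= lo < hi <= 80`.
#' @param correlation_plan data.frame with columns `i`, `j` (column
#'   indices, `i < j`), `intercept` (target correlation at age 20) and
#'   `slope` (change per year), or NULL for no planted pairs.
#' @param background_correlation correlation of all unplanted pairs.
#' @param group_plan optional data.frame with columns `variable` ("sex" or
#'   "ethnicity"), `level`, `i`, `j`, `d_intercept`, `d_slope`: additive
#'   shifts applied to the planted trajectory of pair (i, j) for
#'   participants in that stratum.
#' @param weight_meanlog,weight_sdlog lognormal parameters of the survey
#'   weights (heavy-tailed positive, as in national-survey analysis
#'   weights).
#' @param missing_rate fraction in [0, 1): cells are blanked completely at
#'   random at this rate.
#' @param duplicate_spec optional data.frame with columns `source` (a
#'   biomarker name such as "bm01") and `r` (copy correlation, >= 0.9):
#'   appends a near-duplicate column named `<source>_dup`.
#' @param seed integer; fully determines the output.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_participants = 27508L,
                         n_biomarkers = 50L,
                         age_range = c(20L, 80L),
                         correlation_plan = NULL,
                         background_correlation = 0,
                         group_plan = NULL,
                         weight_meanlog = 0,
                         weight_sdlog = 0.5,
                         missing_rate = 0,
                         duplicate_spec = NULL,
                         seed = 1L) {
  stopifnot(
    n_participants >= 1, n_biomarkers >= 2,
    length(age_range) == 2, age_range[1] >= 20, age_range[2] <= 80,
    age_range[1] < age_range[2],
    missing_rate >= 0, missing_rate < 1,
    abs(background_correlation) <= 0.95
  )
  if (!is.null(correlation_plan)) {
    stopifnot(
      all(c("i", "j", "intercept", "slope") %in% names(correlation_plan)),
      all(correlation_plan$i < correlation_plan$j),
      all(correlation_plan$j <= n_biomarkers)
    )
  }
  if (!is.null(duplicate_spec)) {
    stopifnot(all(duplicate_spec$r >= 0.9), all(duplicate_spec$r <= 0.999))
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_biomarkers = as.integer(n_biomarkers),
      age_range = as.integer(age_range),
      correlation_plan = correlation_plan,
      background_correlation = background_correlation,
      group_plan = group_plan,
      weight_meanlog = weight_meanlog,
      weight_sdlog = weight_sdlog,
      missing_rate = missing_rate,
      duplicate_spec = duplicate_spec,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Nearest positive-semidefinite correlation matrix
#'
#' Projects a symmetric unit-diagonal matrix to the nearest correlation
#' matrix in Frobenius norm (Higham's alternating-projections algorithm,
#' via [Matrix::nearPD()]). A matrix that is already a valid correlation
#' matrix is returned unchanged.
#'
#' @param matrix square symmetric numeric matrix with unit diagonal.
#' @return symmetric unit-diagonal matrix with smallest eigenvalue
#'   >= -1e-10.
#' @export
nearest_psd_correlation <- function(matrix) {
  if (!isSymmetric(unname(matrix), tol = 1e-12)) {
    stop("input must be symmetric")
  }
  ev <- eigen(matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= 0) {
    return(matrix)
  }
  out <- as.matrix(Matrix::nearPD(matrix, corr = TRUE, conv.tol = 1e-8,
                                  maxit = 500)$mat)
  dimnames(out) <- dimnames(matrix)
  out
}

# Target correlation matrix at one age for one stratum: base plan plus
# any group shifts, clipped, then PSD-projected.
planted_corr_at_age <- function(config, age, variable = NULL, level = NULL) {
  p <- config$n_biomarkers
  R <- matrix(config$background_correlation, p, p)
  plan <- config$correlation_plan
  if (!is.null(plan)) {
    for (k in seq_len(nrow(plan))) {
      r <- plan$intercept[k] + plan$slope[k] * (age - 20)
      R[plan$i[k], plan$j[k]] <- r
      R[plan$j[k], plan$i[k]] <- r
    }
  }
  gp <- config$group_plan
  if (!is.null(gp) && !is.null(variable)) {
    sel <- gp$variable == variable & gp$level == level
    for (k in which(sel)) {
      r <- R[gp$i[k], gp$j[k]] + gp$d_intercept[k] + gp$d_slope[k] * (age - 20)
      R[gp$i[k], gp$j[k]] <- r
      R[gp$j[k], gp$i[k]] <- r
    }
  }
  R[R > 0.95] <- 0.95
  R[R < -0.95] <- -0.95
  diag(R) <- 1
  nearest_psd_correlation(R)
}

#' Generate a synthetic cohort with planted age-dependent correlations
#'
#' Ages are uniform over the configured integer range; biomarkers are
#' multivariate Gaussian with the planted correlation matrix at each
#' integer age (per demographic stratum when a group plan is present);
#' survey weights are i.i.d. lognormal; missingness is completely at
#' random; near-duplicate columns are appended last. The global seed is
#' expanded into per-stage child seeds, so the output is reproducible
#' byte for byte.
#'
#' @param config a [synth_config()] object.
#' @return a cohort data.frame: `participant_id`, `age`, `weight`, `sex`,
#'   `ethnicity`, then biomarker columns `bm01`, `bm02`, ...
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_participants
  p <- config$n_biomarkers
  if (config$age_range[1] >= config$age_range[2]) stop("empty age range")

  set.seed(child_seed(config$seed, "ages"))
  age <- sample(seq.int(config$age_range[1], config$age_range[2] - 1L),
                n, replace = TRUE)

  set.seed(child_seed(config$seed, "groups"))
  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(0.511, 0.489))
  ethnicity <- sample(c("white", "hispanic", "black", "other"), n,
                      replace = TRUE, prob = c(0.460, 0.278, 0.200, 0.062))

  set.seed(child_seed(config$seed, "weights"))
  weight <- stats::rlnorm(n, config$weight_meanlog, config$weight_sdlog)

  # Strata over which the correlation matrix differs: only the variables
  # named in the group plan split the cohort; otherwise one stratum.
  gp <- config$group_plan
  if (is.null(gp)) {
    stratum <- rep("all", n)
    stratum_var <- NULL
  } else {
    stratum_var <- unique(gp$variable)
    if (length(stratum_var) > 1) {
      stop("group_plan may target a single demographic variable")
    }
    stratum <- if (stratum_var == "sex") sex else ethnicity
  }

  set.seed(child_seed(config$seed, "biomarkers"))
  X <- matrix(NA_real_, n, p)
  for (s in unique(stratum)) {
    for (a in unique(age[stratum == s])) {
      rows <- which(stratum == s & age == a)
      R <- planted_corr_at_age(config, a,
                               variable = stratum_var,
                               level = if (is.null(stratum_var)) NULL else s)
      L <- chol(R + diag(1e-10, p))
      X[rows, ] <- matrix(stats::rnorm(length(rows) * p),
                          length(rows), p) %*% L
    }
  }
  colnames(X) <- sprintf("bm%02d", seq_len(p))

  if (!is.null(config$duplicate_spec)) {
    set.seed(child_seed(config$seed, "duplicates"))
    for (k in seq_len(nrow(config$duplicate_spec))) {
      src <- config$duplicate_spec$source[k]
      r <- config$duplicate_spec$r[k]
      z <- X[, src]
      z <- (z - mean(z)) / stats::sd(z)
      dup <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
      X <- cbind(X, dup)
      colnames(X)[ncol(X)] <- paste0(src, "_dup")
    }
  }

  if (config$missing_rate > 0) {
    set.seed(child_seed(config$seed, "missing"))
    miss <- matrix(stats::runif(length(X)) < config$missing_rate,
                   nrow(X), ncol(X))
    X[miss] <- NA_real_
  }

  out <- data.frame(
    participant_id = sprintf("P%06d", seq_len(n)),
    age = as.integer(age),
    weight = weight,
    sex = sex,
    ethnicity = ethnicity,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(X))
}

#' Planted correlation of one pair at one age
#'
#' Ground-truth target correlation for a planted pair before PSD
#' projection (projection leaves well-separated plants essentially
#' unchanged). Useful in recovery tests.
#'
#' @param config a [synth_config()].
#' @param i,j column indices of the pair.
#' @param age age in years.
#' @return the clipped linear target correlation.
#' @export
planted_pair_correlation <- function(config, i, j, age) {
  plan <- config$correlation_plan
  r <- config$background_correlation
  if (!is.null(plan)) {
    k <- which(plan$i == min(i, j) & plan$j == max(i, j))
    if (length(k) == 1) {
      r <- plan$intercept[k] + plan$slope[k] * (age - 20)
    }
  }
  min(max(r, -0.95), 0.95)
}
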