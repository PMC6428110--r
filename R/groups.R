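# Baseline and trajectory comparisons of correlations, predictabilities
# and coefficients between demographic strata, with random-split control
# groups as the negative control.

# Split a cohort by a demographic column, or into random control halves.
split_groups <- function(table, by, levels = NULL, seed = 1L) {
  if (identical(by, "control")) {
    return(make_control_groups(table, seed = seed))
  }
  stopifnot(by %in% c("sex", "ethnicity"))
  present <- sort(unique(table[[by]]))
  if (is.null(levels)) {
    if (length(present) < 2) stop("empty group: need two levels of ", by)
    levels <- present[1:2]
  }
  stopifnot(length(levels) == 2)
  a <- table[table[[by]] == levels[1], , drop = FALSE]
  b <- table[table[[by]] == levels[2], , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty group")
  stats::setNames(list(a, b), levels)
}

#' Random-split control groups
#'
#' Seeded uniform partition of the cohort into two halves (sizes differ
#' by at most one). Running the full comparison pipeline on these halves
#' estimates the spurious-finding rate of any demographic contrast.
#'
#' @param table cohort data.frame (>= 2 rows).
#' @param seed integer seed.
#' @return named list of two data.frames (`control1`, `control2`).
#' @export
make_control_groups <- function(table, seed = 1L) {
  n <- nrow(table)
  if (n < 2) stop("need at least 2 rows to split")
  set.seed(child_seed(seed, "controlsplit"))
  idx <- sample.int(n, floor(n / 2))
  list(control1 = table[sort(idx), , drop = FALSE],
       control2 = table[-sort(idx), , drop = FALSE])
}

# z-test comparison of two independent bootstrap estimates:
# var(diff) = var_a + var_b.
compare_estimates <- function(id, est_a, sd_a, est_b, sd_b, family_size) {
  d <- est_a - est_b
  se <- sqrt(sd_a^2 + sd_b^2)
  z <- d / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(
    id = id, est_a = est_a, est_b = est_b,
    diff = d, diff_se = se, z = z, p = p,
    corrected_p = p * family_size,
    neg_log_corrected_p = neg_log_corrected_p(p, family_size),
    significant = p * family_size < 0.05,
    stringsAsFactors = FALSE
  )
}

# Full-age-range weighted correlations of one group with bootstrap SDs.
group_corr_baseline <- function(table, B, seed) {
  bms <- biomarker_names(table)
  pairs <- pair_table(bms)
  X <- as.matrix(table[, bms, drop = FALSE])
  w <- table$weight
  est <- pair_values(weighted_corr_matrix(X, w), pairs)
  set.seed(child_seed(seed, "baselineboot"))
  list(pairs = pairs, est = est, sd = corr_boot_se(X, w, pairs, B))
}

#' Baseline differences of a quantity between two groups
#'
#' Computes the quantity (pairwise correlations, predictabilities, or
#' regression coefficients) on the full age range separately in each
#' group, with bootstrap standard deviations, and tests each identifier
#' with `z = (est_a - est_b) / sqrt(sd_a^2 + sd_b^2)` against a normal
#' reference, Bonferroni-correcting over the quantity's own family
#' (number of pairs, of biomarkers, or of ordered biomarker pairs). The
#' two groups are first equalized to a common sample size (seeded
#' subsampling of the larger group) so estimates are comparable.
#'
#' @param table preprocessed cohort data.frame.
#' @param by `"sex"`, `"ethnicity"`, or `"control"`.
#' @param quantity `"correlation"`, `"r2"`, or `"coefficient"`.
#' @param B bootstrap replicates (correlation) / parametric-bootstrap
#'   replicates (coefficient); for `"r2"` the R^2 bootstrap uses
#'   `config$boot_B`.
#' @param seed integer seed.
#' @param levels the two levels to compare (default: first two).
#' @param config a [predict_config()] (r2 / coefficient only).
#' @return data.frame of comparison rows (one per identifier) with
#'   attribute `groups` naming the compared strata.
#' @export
baseline_difference <- function(table, by = "sex",
                                quantity = c("correlation", "r2",
                                             "coefficient"),
                                B = 1000L, seed = 1L, levels = NULL,
                                config = predict_config()) {
  quantity <- match.arg(quantity)
  gs <- split_groups(table, by, levels = levels, seed = seed)
  n_min <- min(nrow(gs[[1]]), nrow(gs[[2]]))
  # all per-group seeds are keyed by the group's label, not its position,
  # so swapping group_a/group_b flips every sign exactly
  for (k in 1:2) {
    if (nrow(gs[[k]]) > n_min) {
      set.seed(child_seed(seed, paste0("equalize", names(gs)[k])))
      gs[[k]] <- gs[[k]][sort(sample.int(nrow(gs[[k]]), n_min)), ,
                         drop = FALSE]
    }
  }
  bms <- biomarker_names(table)

  if (quantity == "correlation") {
    a <- group_corr_baseline(gs[[1]], B,
                             child_seed(seed, paste0("g", names(gs)[1])))
    b <- group_corr_baseline(gs[[2]], B,
                             child_seed(seed, paste0("g", names(gs)[2])))
    out <- compare_estimates(a$pairs$pair, a$est, a$sd, b$est, b$sd,
                             family_size = nrow(a$pairs))
  } else if (quantity == "r2") {
    rec <- lapply(1:2, function(k) {
      do.call(rbind, lapply(bms, function(tg) {
        cross_fit_r2(gs[[k]], tg, config,
                     seed = child_seed(seed, paste0("r2g", names(gs)[k])))
      }))
    })
    out <- compare_estimates(rec[[1]]$target,
                             rec[[1]]$r2, rec[[1]]$r2_se,
                             rec[[2]]$r2, rec[[2]]$r2_se,
                             family_size = length(bms))
  } else {
    rec <- lapply(1:2, function(k) {
      do.call(rbind, lapply(bms, function(tg) {
        fit <- fit_full_coefficients(
          gs[[k]], tg, config,
          seed = child_seed(seed, paste0("cfg", names(gs)[k])))
        parametric_bootstrap_se(
          fit, B = B,
          seed = child_seed(seed, paste0("cbg", names(gs)[k], tg)))
      }))
    })
    id <- paste(rec[[1]]$target, rec[[1]]$predictor, sep = "<-")
    out <- compare_estimates(id,
                             rec[[1]]$coefficient, rec[[1]]$se,
                             rec[[2]]$coefficient, rec[[2]]$se,
                             family_size = length(bms) * (length(bms) - 1))
  }
  attr(out, "groups") <- names(gs)
  out
}

#' Trajectory differences of per-age correlations between two groups
#'
#' Per common age bin (bins present in both groups, each equalized to
#' the smaller group's bin count), the difference of the two groups'
#' weighted correlations is formed with variance equal to the sum of the
#' two bootstrap variances; each pair's difference series is then
#' meta-regressed on age and Bonferroni-corrected over the pair family.
#'
#' @param table preprocessed cohort data.frame.
#' @param by `"sex"`, `"ethnicity"`, or `"control"`.
#' @param B bootstrap replicates per bin and group.
#' @param seed integer seed.
#' @param min_n minimum equalized bin size.
#' @param levels the two levels to compare.
#' @return data.frame (one row per pair): pair, slope of the difference,
#'   slope_se, z, p, corrected_p, neg_log_corrected_p, class of the
#'   difference trajectory, significant flag; attribute `groups`.
#' @export
trajectory_difference <- function(table, by = "sex", B = 1000L, seed = 1L,
                                  min_n = 100L, levels = NULL) {
  gs <- split_groups(table, by, levels = levels, seed = seed)
  # common bin grid, equalized within-bin sample sizes
  ages_a <- table(gs[[1]]$age); ages_b <- table(gs[[2]]$age)
  common <- intersect(names(ages_a), names(ages_b))
  common <- common[pmin(ages_a[common], ages_b[common]) >= min_n]
  if (length(common) < 3) stop("fewer than 3 common age bins at min_n")
  common_ages <- sort(as.integer(common))
  eq <- lapply(1:2, function(k) {
    g <- gs[[k]][gs[[k]]$age %in% common_ages, , drop = FALSE]
    keep <- unlist(lapply(common_ages, function(a) {
      rows <- which(g$age == a)
      quota <- min(ages_a[as.character(a)], ages_b[as.character(a)])
      set.seed(child_seed(seed, paste0("eqbin", names(gs)[k], a)))
      sample(rows, quota)
    }))
    g[sort(keep), , drop = FALSE]
  })
  pa <- corr_panel_series(eq[[1]], B = B,
                          seed = child_seed(seed,
                                            paste0("panel", names(gs)[1])),
                          min_n = min_n)
  pb <- corr_panel_series(eq[[2]], B = B,
                          seed = child_seed(seed,
                                            paste0("panel", names(gs)[2])),
                          min_n = min_n)
  stopifnot(identical(pa$ages, pb$ages))
  D <- pa$est - pb$est
  S <- sqrt(pa$se^2 + pb$se^2)
  fits <- meta_regress_matrix(D, S, pa$ages, family_size = nrow(pa$pairs))
  out <- cbind(pa$pairs, fits)
  out$significant <- out$corrected_p < 0.05
  attr(out, "groups") <- names(gs)
  attr(out, "ages") <- pa$ages
  out
}

#' Trajectory difference of two pre-computed series
#'
#' Generic comparison for quantities already summarized as per-age
#' estimate/SE series in each group (e.g. per-window predictabilities or
#' coefficients): the per-age difference, with variance the sum of the
#' two variances, is meta-regressed on age.
#'
#' @param series_a,series_b data.frames with columns `age`, `estimate`,
#'   `se` on a common age grid.
#' @param family_size Bonferroni family size.
#' @return one-row data.frame of trajectory-fit fields for the
#'   difference.
#' @export
compare_series <- function(series_a, series_b, family_size = 1L) {
  stopifnot(identical(series_a$age, series_b$age))
  meta_regress(
    data.frame(age = series_a$age,
               estimate = series_a$estimate - series_b$estimate,
               se = sqrt(series_a$se^2 + series_b$se^2)),
    family_size = family_size
  )
}
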