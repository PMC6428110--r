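# Preprocessing: reduce a raw cohort table to a complete, gaussianized,
# survey-weight-standardized analysis matrix, logging every decision.

new_preprocess_report <- function(step, ...) {
  structure(c(list(step = step), list(...)), class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report:", x$step, ">\n")
  for (nm in setdiff(names(x), "step")) {
    v <- x[[nm]]
    if (is.atomic(v) && length(v) <= 12) {
      cat("  ", nm, ": ", paste(v, collapse = ", "), "\n", sep = "")
    } else {
      cat("  ", nm, ": <", class(v)[1], " of length ", length(v), ">\n",
          sep = "")
    }
  }
  invisible(x)
}

#' Iteratively extract a complete matrix
#'
#' Repeatedly removes whichever entity — the row or the biomarker column
#' with the highest missing fraction — is worse, until no missing cells
#' remain. At a tie the row is removed (keeping more biomarkers). All
#' removals are logged.
#'
#' @param table a cohort data.frame (may contain NA biomarker cells).
#' @return list with `table` (complete) and `report` (a
#'   `preprocess_report` with `dropped_samples`, `dropped_biomarkers`).
#' @export
complete_matrix <- function(table) {
  bms <- biomarker_names(table)
  dropped_samples <- character(0)
  dropped_biomarkers <- character(0)
  repeat {
    M <- is.na(as.matrix(table[, bms, drop = FALSE]))
    if (nrow(M) == 0 || length(bms) == 0) {
      stop("complete_matrix: everything removed; dropped ",
           length(dropped_samples), " samples and ",
           length(dropped_biomarkers), " biomarkers")
    }
    if (!any(M)) break
    row_frac <- rowMeans(M)
    col_frac <- colMeans(M)
    if (max(row_frac) >= max(col_frac)) {
      k <- which.max(row_frac)
      dropped_samples <- c(dropped_samples, table$participant_id[k])
      table <- table[-k, , drop = FALSE]
    } else {
      k <- which.max(col_frac)
      dropped_biomarkers <- c(dropped_biomarkers, bms[k])
      table[[bms[k]]] <- NULL
      bms <- bms[-k]
    }
  }
  rownames(table) <- NULL
  list(
    table = table,
    report = new_preprocess_report(
      "complete_matrix",
      dropped_samples = dropped_samples,
      dropped_biomarkers = dropped_biomarkers
    )
  )
}

#' Drop biomarkers that are redundant with an earlier column
#'
#' Greedy scan of biomarker pairs in input column order: whenever the
#' absolute survey-weighted correlation of a pair exceeds `threshold`,
#' the later column is dropped and the earlier one kept. The surviving
#' panel has no pair above the threshold.
#'
#' @param table complete cohort data.frame.
#' @param threshold drop threshold on |weighted r|, in (0, 1].
#' @return list with `table` and `report` (dropped biomarkers with the
#'   partner that triggered the drop).
#' @export
drop_redundant <- function(table, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  bms <- biomarker_names(table)
  R <- weighted_corr_matrix(table[, bms, drop = FALSE], table$weight)
  keep <- rep(TRUE, length(bms))
  reason <- character(0)
  dropped <- character(0)
  for (i in seq_along(bms)) {
    if (!keep[i]) next
    for (j in seq_along(bms)) {
      if (j <= i || !keep[j]) next
      if (abs(R[i, j]) > threshold) {
        keep[j] <- FALSE
        dropped <- c(dropped, bms[j])
        reason <- c(reason, sprintf("|r|=%.3f with %s", abs(R[i, j]), bms[i]))
      }
    }
  }
  out <- table[, c(META_COLS[META_COLS %in% names(table)], bms[keep])]
  list(
    table = out,
    report = new_preprocess_report(
      "drop_redundant",
      dropped_biomarkers = dropped,
      reason = reason,
      threshold = threshold
    )
  )
}

# Candidate transforms for gaussianize(). The log candidate shifts
# non-positive columns by min + eps (eps = 1e-6 * range, recorded); the
# exp candidate is centered first (skewness-invariant) so it cannot
# overflow on typical scales; if it still would, it drops out of the
# running via an infinite skewness score.
transform_candidates <- function(x, w) {
  m <- weighted_mean(x, w)
  shift <- if (min(x) > 0) 0 else -min(x) + 1e-6 * (max(x) - min(x))
  ex <- if (max(x - m) < 700) exp(x - m) else rep(Inf, length(x))
  list(
    identity = list(values = x, shift = 0),
    log = list(values = log(x + shift), shift = shift),
    exp = list(values = ex, center = m)
  )
}

#' Choose gaussianizing transforms per biomarker
#'
#' For each biomarker, picks among identity, logarithmic and exponential
#' transforms the one minimizing the absolute survey-weighted skewness,
#' and applies it. The log transform shifts non-positive columns by
#' `min + 1e-6 * range` (recorded); the exponential transform is applied
#' after centering (which leaves skewness unchanged but prevents
#' overflow).
#'
#' @param table complete cohort data.frame.
#' @return list with `table` (transformed) and `report` (chosen transform
#'   and parameters per biomarker).
#' @export
gaussianize <- function(table) {
  bms <- biomarker_names(table)
  choice <- character(length(bms))
  params <- vector("list", length(bms))
  names(choice) <- names(params) <- bms
  for (b in bms) {
    cand <- transform_candidates(table[[b]], table$weight)
    sk <- vapply(cand, function(cc) {
      v <- cc$values
      if (any(!is.finite(v))) return(Inf)
      abs(weighted_skewness(v, table$weight))
    }, numeric(1))
    best <- names(which.min(sk))
    if (!is.finite(min(sk))) stop("non-finite values for biomarker ", b)
    choice[b] <- best
    params[[b]] <- cand[[best]][setdiff(names(cand[[best]]), "values")]
    table[[b]] <- cand[[best]]$values
  }
  list(
    table = table,
    report = new_preprocess_report(
      "gaussianize",
      transform_per_biomarker = choice,
      params = params
    )
  )
}

#' Center and scale biomarkers using the survey weights
#'
#' Each biomarker is shifted and scaled so its survey-weighted mean is 0
#' and its survey-weighted variance is 1 (weights normalized to sum to
#' one). The means and SDs used are recorded so the standardization can
#' be replayed exactly.
#'
#' @param table complete cohort data.frame.
#' @return list with `table` and `report` (`weighted_means`,
#'   `weighted_sds`).
#' @export
weighted_standardize <- function(table) {
  bms <- biomarker_names(table)
  mu <- sd <- numeric(length(bms))
  names(mu) <- names(sd) <- bms
  for (b in bms) {
    mu[b] <- weighted_mean(table[[b]], table$weight)
    v <- weighted_var(table[[b]], table$weight)
    if (v <= 0) stop("zero weighted variance in biomarker ", b)
    sd[b] <- sqrt(v)
    table[[b]] <- (table[[b]] - mu[b]) / sd[b]
  }
  list(
    table = table,
    report = new_preprocess_report(
      "weighted_standardize",
      weighted_means = mu,
      weighted_sds = sd
    )
  )
}

#' Average groups of repeated-measure columns
#'
#' Generic pre-step for repeated measures (e.g. several blood-pressure
#' readings): each entry of `map` names an output column built as the
#' row-wise mean of the listed input columns, which are then removed.
#'
#' @param table cohort data.frame.
#' @param map named list: `list(out_name = c("in1", "in2", ...))`.
#' @return the modified data.frame.
#' @export
average_repeats <- function(table, map) {
  for (out in names(map)) {
    ins <- map[[out]]
    stopifnot(all(ins %in% names(table)))
    table[[out]] <- rowMeans(table[, ins, drop = FALSE])
    table[setdiff(ins, out)] <- NULL
  }
  table
}

#' Full preprocessing pipeline
#'
#' Completeness extraction, redundancy filter, gaussianizing transforms
#' and weighted standardization, in that order, with a combined report.
#'
#' @param table raw cohort data.frame.
#' @param redundancy_threshold |weighted r| above which the later of a
#'   pair of biomarkers is dropped.
#' @return list with `table` (analysis-ready) and `reports` (list of the
#'   four stage reports).
#' @export
preprocess <- function(table, redundancy_threshold = 0.9) {
  s1 <- complete_matrix(table)
  s2 <- drop_redundant(s1$table, redundancy_threshold)
  s3 <- gaussianize(s2$table)
  s4 <- weighted_standardize(s3$table)
  list(
    table = s4$table,
    reports = list(
      complete_matrix = s1$report,
      drop_redundant = s2$report,
      gaussianize = s3$report,
      weighted_standardize = s4$report
    )
  )
}

#' Weighted linear association of each biomarker with age
#'
#' Survey-weighted least-squares regression of each standardized biomarker
#' on standardized age. Slopes are reported both per sd/year
#' (`slope`) and on the conventional display scale multiplied by 100
#' (`slope_x100`). P-values are Bonferroni-corrected over the number of
#' biomarkers; negative log corrected p-values are capped at 308.
#'
#' @param table standardized cohort data.frame.
#' @return data.frame: biomarker, r (weighted Pearson with age), slope,
#'   slope_x100, p, corrected_p, neg_log_corrected_p.
#' @export
biomarker_age_association <- function(table) {
  if (length(unique(table$age)) < 3) stop("fewer than 3 distinct ages")
  bms <- biomarker_names(table)
  wn <- norm_weights(table$weight)
  a <- table$age
  am <- sum(wn * a)
  av <- sum(wn * (a - am)^2)
  az <- (a - am) / sqrt(av)
  n <- nrow(table)
  out <- lapply(bms, function(b) {
    y <- table[[b]]
    ym <- sum(wn * y)
    yv <- sum(wn * (y - ym)^2)
    yz <- (y - ym) / sqrt(yv)
    r <- sum(wn * az * yz)
    # WLS of standardized y on standardized age: slope equals r; its
    # classical standard error from the weighted residual variance.
    fit <- stats::lm(yz ~ az, weights = wn)
    sm <- summary(fit)$coefficients
    p <- sm["az", "Pr(>|t|)"]
    data.frame(
      biomarker = b, r = r, slope = r, slope_x100 = 100 * r,
      p = p, corrected_p = p * length(bms),
      neg_log_corrected_p = neg_log_corrected_p(p, length(bms)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
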