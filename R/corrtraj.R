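# Age trajectories of pairwise correlations: per-age survey-weighted
# Pearson correlations with bootstrap standard errors, inverse-variance
# meta-regression of each series on age, and a six-class taxonomy of
# significant trends.

#' Survey-weighted Pearson correlation
#'
#' `r = sum(wn (x - xbar_w)(y - ybar_w)) / sqrt(sum(wn (x - xbar_w)^2) *
#' sum(wn (y - ybar_w)^2))` with `wn = w / sum(w)`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param w strictly positive weights.
#' @return correlation in [-1, 1]. Errors (rather than returning NaN) if
#'   either variable is constant under the weights.
#' @export
weighted_pearson <- function(x, y, w) {
  if (length(x) != length(y) || length(x) != length(w)) {
    stop("x, y, w must have equal lengths")
  }
  if (length(x) < 3) stop("need at least 3 observations")
  wn <- norm_weights(w)
  xm <- sum(wn * x); ym <- sum(wn * y)
  sx <- sum(wn * (x - xm)^2); sy <- sum(wn * (y - ym)^2)
  if (sx <= 0 || sy <= 0) stop("constant input: correlation undefined")
  r <- sum(wn * (x - xm) * (y - ym)) / sqrt(sx * sy)
  min(max(r, -1), 1)
}

# Bootstrap SD of every pairwise weighted correlation of X under row
# resampling with replacement (weights carried, renormalized within each
# resample). All resamples are reduced to weighted first/second moments
# with a single rowsum() accumulation per chunk, which is algebraically
# identical to recomputing weighted_corr_matrix per resample. Degenerate
# resamples (a constant column) yield NaN and are dropped from the SD.
corr_boot_se <- function(X, w, pairs, B) {
  n <- nrow(X)
  p <- ncol(X)
  M <- cbind(w, w * X, w * X^2, w * X[, pairs$i] * X[, pairs$j])
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  chunk <- max(1L, min(B, floor(8e6 / (n * ncol(M)))))
  boot <- matrix(NA_real_, B, nrow(pairs))
  for (b0 in seq(1L, B, by = chunk)) {
    bs <- b0:min(b0 + chunk - 1L, B)
    g <- rowsum(M[as.vector(idx[, bs, drop = FALSE]), , drop = FALSE],
                group = rep(seq_along(bs), each = n))
    Sw <- g[, 1]
    mu <- g[, 1 + seq_len(p), drop = FALSE] / Sw
    v <- g[, 1 + p + seq_len(p), drop = FALSE] / Sw - mu^2
    cross <- g[, 1 + 2 * p + seq_len(nrow(pairs)), drop = FALSE] / Sw -
      mu[, pairs$i, drop = FALSE] * mu[, pairs$j, drop = FALSE]
    denom <- sqrt(v[, pairs$i, drop = FALSE] * v[, pairs$j, drop = FALSE])
    denom[denom <= 0] <- NaN
    boot[bs, ] <- pmin(pmax(cross / denom, -1), 1)
  }
  apply(boot, 2, stats::sd, na.rm = TRUE)
}

#' Per-age correlation panel with bootstrap standard errors
#'
#' For every integer age (bin) with at least `min_n` participants, the
#' weighted Pearson correlation of every biomarker pair is computed, along
#' with a bootstrap standard error: rows are resampled with replacement
#' within the bin (each row keeps its survey weight; weights renormalize
#' within the resample) `B` times and the SE is the standard deviation of
#' the resampled estimates.
#'
#' @param table preprocessed cohort data.frame.
#' @param B number of bootstrap replicates per bin.
#' @param seed integer seed; expanded deterministically per bin.
#' @param min_n bins with fewer rows are skipped (with a warning).
#' @param columns optional character vector restricting the biomarker
#'   panel.
#' @return object of class `corr_panel`: list with `ages`, `n` (bin
#'   sizes), `pairs` (pair table), `est` and `se` (bins x pairs matrices),
#'   `B`, `seed`.
#' @export
corr_panel_series <- function(table, B = 1000L, seed = 1L, min_n = 100L,
                              columns = NULL) {
  bms <- if (is.null(columns)) biomarker_names(table) else columns
  pairs <- pair_table(bms)
  ages_all <- sort(unique(table$age))
  counts <- vapply(ages_all, function(a) sum(table$age == a), integer(1))
  skipped <- ages_all[counts < min_n]
  if (length(skipped) > 0) {
    warning("skipping ", length(skipped), " age bin(s) below min_n = ",
            min_n, ": ", paste(skipped, collapse = ", "))
  }
  ages <- ages_all[counts >= min_n]
  if (length(ages) == 0) stop("no age bin meets min_n")

  est <- se <- matrix(NA_real_, length(ages), nrow(pairs))
  n_bin <- integer(length(ages))
  for (k in seq_along(ages)) {
    rows <- which(table$age == ages[k])
    n_bin[k] <- length(rows)
    X <- as.matrix(table[rows, bms, drop = FALSE])
    w <- table$weight[rows]
    est[k, ] <- pair_values(weighted_corr_matrix(X, w), pairs)
    set.seed(child_seed(seed, paste0("corrbin", ages[k])))
    se[k, ] <- corr_boot_se(X, w, pairs, B)
  }
  structure(
    list(ages = ages, n = n_bin, pairs = pairs, est = est, se = se,
         B = B, seed = seed),
    class = "corr_panel"
  )
}

#' Bootstrap correlation series for a single biomarker pair
#'
#' Convenience wrapper around [corr_panel_series()] for one pair.
#'
#' @param table preprocessed cohort data.frame.
#' @param pair character vector of two biomarker names.
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @param min_n minimum bin size.
#' @return data.frame of age-bin estimates: `age`, `estimate`, `se`, `n`.
#' @export
bootstrap_corr_series <- function(table, pair, B = 1000L, seed = 1L,
                                  min_n = 100L) {
  stopifnot(length(pair) == 2, all(pair %in% biomarker_names(table)))
  panel <- corr_panel_series(table, B = B, seed = seed, min_n = min_n,
                             columns = pair)
  data.frame(
    age = panel$ages,
    estimate = panel$est[, 1],
    se = panel$se[, 1],
    n = panel$n
  )
}

#' Six-class taxonomy of significant age trends
#'
#' A trajectory is classified only when its Bonferroni-corrected p-value
#' is below 0.05; otherwise the class is `none`. Significant trends are
#' labelled by the slope sign and the signs of the fitted values at the
#' youngest and oldest ages: `dec_pp` (decreases, remains positive),
#' `dec_pn` (decreases, switches sign), `dec_nn` (decreases, remains
#' negative), `inc_nn`, `inc_np`, `inc_pp`. An endpoint exactly at zero
#' inherits the other endpoint's sign (broken toward the non-switching
#' class).
#'
#' @param slope,start_value,end_value,corrected_p numeric vectors.
#' @return character vector of class labels.
#' @export
classify_trajectory <- function(slope, start_value, end_value, corrected_p) {
  n <- length(slope)
  out <- rep("none", n)
  sig <- corrected_p < 0.05 & slope != 0
  ss <- sign(start_value); es <- sign(end_value)
  ss[ss == 0] <- es[ss == 0]
  es[es == 0] <- ss[es == 0]
  lab <- ifelse(slope < 0,
    ifelse(ss > 0, ifelse(es > 0, "dec_pp", "dec_pn"), "dec_nn"),
    ifelse(ss < 0, ifelse(es < 0, "inc_nn", "inc_np"), "inc_pp")
  )
  out[sig] <- lab[sig]
  out
}

# Vectorized WLS meta-regression over the columns of an estimate matrix
# E (bins x series) with SE matrix S; weights 1/S^2. Because the per-bin
# SEs are themselves bootstrap estimates (noisy, and slightly downward
# biased in finite bins), the nominal inverse-variance slope SE is
# inflated by the estimated residual dispersion max(1, Q/df) — the scale
# a weighted lm() would estimate, floored at the known-variance value —
# and the slope is referred to a t distribution on df = bins - 2. On
# exact or under-dispersed series this reduces to fixed-effect WLS.
meta_regress_matrix <- function(E, S, ages, family_size) {
  stopifnot(nrow(E) == length(ages), all(dim(E) == dim(S)))
  if (length(ages) < 3) stop("need at least 3 age bins")
  if (any(!is.finite(S)) || any(S < 0)) stop("non-finite or negative SE")
  if (any(colSums(S > 0) == 0)) stop("all standard errors are zero")
  W <- 1 / S^2
  x <- ages
  Sw <- colSums(W)
  Swx <- colSums(W * x)
  Swx2 <- colSums(W * x^2)
  Swy <- colSums(W * E)
  Swxy <- colSums(W * x * E)
  det <- Sw * Swx2 - Swx^2
  slope <- (Sw * Swxy - Swx * Swy) / det
  intercept <- (Swx2 * Swy - Swx * Swxy) / det
  k <- length(ages)
  resid <- E - (rep(1, k) %o% intercept + x %o% slope)
  Q <- colSums(W * resid^2)
  scale2 <- pmax(1, Q / (k - 2))
  slope_se <- sqrt(Sw / det * scale2)
  z <- slope / slope_se
  p <- 2 * stats::pt(-abs(z), df = k - 2)
  corrected_p <- p * family_size
  start_value <- intercept + slope * min(x)
  end_value <- intercept + slope * max(x)
  data.frame(
    slope = slope, slope_se = slope_se, intercept = intercept,
    z = z, p = p, corrected_p = corrected_p,
    neg_log_corrected_p = neg_log_corrected_p(p, family_size),
    start_value = start_value, end_value = end_value,
    class = classify_trajectory(slope, start_value, end_value, corrected_p),
    stringsAsFactors = FALSE
  )
}

#' Meta-regression of an age-binned series on age
#'
#' Weighted least squares of the per-bin estimates on age, each bin
#' weighted by the inverse of its bootstrap variance, with the slope SE
#' inflated by the estimated residual dispersion (floored at the
#' known-variance fixed-effect value) and the slope tested against zero
#' on a t reference with `bins - 2` degrees of freedom. The p-value is
#' Bonferroni-corrected by multiplying by `family_size` (deliberately not
#' clamped at 1). Start and end values are the fitted line at the
#' youngest and oldest bins, and the trend is classified with
#' [classify_trajectory()].
#'
#' @param series data.frame with columns `age`, `estimate`, `se` (as
#'   returned by [bootstrap_corr_series()]).
#' @param family_size Bonferroni family size.
#' @return one-row data.frame: slope, slope_se, intercept, z, p,
#'   corrected_p, neg_log_corrected_p, start_value, end_value, class.
#' @export
meta_regress <- function(series, family_size = 1L) {
  stopifnot(all(c("age", "estimate", "se") %in% names(series)))
  meta_regress_matrix(
    matrix(series$estimate, ncol = 1),
    matrix(series$se, ncol = 1),
    series$age, family_size
  )
}

#' Trajectory fits for the full correlation panel
#'
#' Runs [corr_panel_series()] and meta-regresses every pair's correlation
#' series on age, Bonferroni-correcting over the number of pairs.
#'
#' @param table preprocessed cohort data.frame.
#' @param B bootstrap replicates per bin.
#' @param seed integer seed.
#' @param min_n minimum bin size.
#' @param family_size Bonferroni family size; defaults to the number of
#'   pairs in the panel.
#' @return list with `panel` (the `corr_panel`) and `fits` (data.frame,
#'   one row per pair, with pair names and all trajectory-fit fields).
#' @export
corr_trajectories <- function(table, B = 1000L, seed = 1L, min_n = 100L,
                              family_size = NULL) {
  panel <- corr_panel_series(table, B = B, seed = seed, min_n = min_n)
  if (is.null(family_size)) family_size <- nrow(panel$pairs)
  fits <- meta_regress_matrix(panel$est, panel$se, panel$ages, family_size)
  fits <- cbind(panel$pairs, fits)
  list(panel = panel, fits = fits)
}

#' Trend in the mean absolute correlation with age
#'
#' Per age bin, the mean and SD of |r| across the pairs of the panel;
#' the mean is meta-regressed on age with SE = SD / sqrt(number of
#' pairs). Optionally restricted to the pairs whose own trajectories are
#' significant.
#'
#' @param panel a `corr_panel`.
#' @param fits optional trajectory-fit data.frame (from
#'   [corr_trajectories()]); required when `restrict_to_significant`.
#' @param restrict_to_significant if TRUE, only pairs with class != none.
#' @return list with `series` (age, estimate = mean |r|, sd, se, n_pairs)
#'   and `fit` (one-row meta-regression data.frame, family size 1).
#' @export
mean_abs_corr_trend <- function(panel, fits = NULL,
                                restrict_to_significant = FALSE) {
  A <- abs(panel$est)
  if (restrict_to_significant) {
    if (is.null(fits)) stop("fits required to restrict to significant pairs")
    keep <- fits$class != "none"
    if (!any(keep)) stop("no significant pairs to restrict to")
    A <- A[, keep, drop = FALSE]
  }
  m <- rowMeans(A)
  s <- apply(A, 1, stats::sd)
  series <- data.frame(
    age = panel$ages, estimate = m, sd = s,
    se = s / sqrt(ncol(A)), n_pairs = ncol(A)
  )
  list(series = series, fit = meta_regress(series, family_size = 1L))
}
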