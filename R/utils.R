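# Internal helpers shared across modules: deterministic seed derivation,
# survey-weighted moments, and biomarker-pair bookkeeping.

# Columns of a cohort table that are metadata, not biomarkers.
META_COLS <- c("participant_id", "age", "weight", "sex", "ethnicity")

#' Names of the biomarker columns of a cohort table
#'
#' A cohort table is a plain data.frame whose non-metadata columns
#' (everything except `participant_id`, `age`, `weight`, `sex`,
#' `ethnicity`) are numeric biomarkers.
#'
#' @param table a cohort data.frame.
#' @return character vector of biomarker column names, in table order.
#' @export
biomarker_names <- function(table) {
  setdiff(names(table), META_COLS)
}

#' Derive a child seed from a global seed and a stage label
#'
#' One global seed is expanded into independent per-stage seeds by a fixed
#' affine congruential scheme so that adding a stage never perturbs the
#' draws of another. The result always lies in [1, 2^31 - 2].
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer child seed.
#' @export
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) %% 2147483647 * 69069 + h * 10007) %% 2147483629 + 1)
}

# Normalize weights to sum to one; validates positivity.
norm_weights <- function(w) {
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be strictly positive and finite")
  }
  w / sum(w)
}

#' Survey-weighted mean, variance and skewness
#'
#' Population-style weighted moments with weights normalized to sum to one:
#' these are invariant to duplicating a row while halving its weight.
#'
#' @param x numeric vector.
#' @param w positive weights, same length.
#' @return for `weighted_mean`/`weighted_var`/`weighted_skewness`, a scalar.
#' @export
weighted_mean <- function(x, w) {
  wn <- norm_weights(w)
  sum(wn * x)
}

#' @rdname weighted_mean
#' @export
weighted_var <- function(x, w) {
  wn <- norm_weights(w)
  m <- sum(wn * x)
  sum(wn * (x - m)^2)
}

#' @rdname weighted_mean
#' @export
weighted_skewness <- function(x, w) {
  wn <- norm_weights(w)
  m <- sum(wn * x)
  s2 <- sum(wn * (x - m)^2)
  if (s2 <= 0) stop("zero weighted variance: skewness undefined")
  sum(wn * (x - m)^3) / s2^1.5
}

#' Survey-weighted correlation matrix
#'
#' Weighted Pearson correlations between all columns of a numeric matrix,
#' with weights normalized to sum to one.
#'
#' @param X numeric matrix (rows = participants, columns = biomarkers).
#' @param w positive weights, length `nrow(X)`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
weighted_corr_matrix <- function(X, w) {
  X <- as.matrix(X)
  wn <- norm_weights(w)
  mu <- colSums(X * wn)
  Xc <- sweep(X, 2L, mu, "-")
  sd <- sqrt(colSums(Xc^2 * wn))
  if (any(sd == 0)) stop("constant column: correlation undefined")
  Z <- sweep(Xc, 2L, sd, "/") * sqrt(wn)
  R <- crossprod(Z)
  diag(R) <- 1
  R[R > 1] <- 1
  R[R < -1] <- -1
  R
}

# All unordered biomarker pairs in canonical order (1,2),(1,3),...,(p-1,p).
pair_table <- function(nms) {
  idx <- utils::combn(length(nms), 2L)
  data.frame(
    i = idx[1L, ], j = idx[2L, ],
    pair = paste(nms[idx[1L, ]], nms[idx[2L, ]], sep = "~"),
    stringsAsFactors = FALSE
  )
}

# Extract the canonical pair vector from a correlation matrix.
pair_values <- function(R, pairs) {
  R[cbind(pairs$i, pairs$j)]
}

# Half-away-from-zero rounding at `digits` decimals (so 0.15 -> 0.2).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
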