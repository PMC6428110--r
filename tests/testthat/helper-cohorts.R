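# Builders for small in-memory cohort tables used across the suite.

# Wrap a biomarker matrix in the cohort-table layout.
make_cohort <- function(X, age = NULL, weight = NULL, sex = NULL,
                        ethnicity = NULL) {
  n <- nrow(X)
  cn <- colnames(X)
  if (is.null(cn)) cn <- rep("", ncol(X))
  cn[cn == ""] <- sprintf("bm%02d", seq_len(ncol(X)))[cn == ""]
  colnames(X) <- cn
  data.frame(
    participant_id = sprintf("P%06d", seq_len(n)),
    age = if (is.null(age)) rep(50L, n) else as.integer(age),
    weight = if (is.null(weight)) rep(1, n) else weight,
    sex = if (is.null(sex)) rep("female", n) else sex,
    ethnicity = if (is.null(ethnicity)) rep("white", n) else ethnicity,
    X,
    stringsAsFactors = FALSE
  )
}

# n x p matrix whose *sample* correlation matrix is exactly R: orthonormal
# centered columns rotated by chol(R).
exact_corr_data <- function(n, R, seed = 1) {
  set.seed(seed)
  p <- nrow(R)
  M <- matrix(rnorm(n * (p + 1)), n, p + 1)
  M <- sweep(M, 2, colMeans(M))
  Q <- qr.Q(qr(M))[, seq_len(p), drop = FALSE]
  X <- Q %*% chol(R) * sqrt(n - 1)
  colnames(X) <- sprintf("bm%02d", seq_len(p))
  X
}

# Equal off-diagonal correlation matrix.
const_corr <- function(p, r) {
  R <- matrix(r, p, p)
  diag(R) <- 1
  R
}
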