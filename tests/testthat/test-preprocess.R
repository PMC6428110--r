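# Preprocessing: completeness extraction, redundancy filter, transforms,
# weighted standardization, age associations.

# Independent re-implementation of the greedy completeness rule, used as
# an oracle: compare worst row vs worst column missing fraction, remove
# the worse (row at ties), repeat.
brute_force_complete <- function(M) {
  rows <- seq_len(nrow(M)); cols <- seq_len(ncol(M))
  repeat {
    sub <- M[rows, cols, drop = FALSE]
    if (!any(is.na(sub))) break
    rf <- rowMeans(is.na(sub)); cf <- colMeans(is.na(sub))
    if (max(rf) >= max(cf)) rows <- rows[-which.max(rf)]
    else cols <- cols[-which.max(cf)]
  }
  list(rows = rows, cols = cols)
}

test_that("complete input passes through complete_matrix unchanged", {
  tb <- make_cohort(matrix(rnorm(60), 20, 3))
  out <- complete_matrix(tb)
  expect_identical(out$table, tb)
  expect_length(out$report$dropped_samples, 0)
  expect_length(out$report$dropped_biomarkers, 0)
})

test_that("a dominantly missing column is dropped before any row", {
  X <- matrix(rnorm(15), 5, 3)
  X[1:4, 2] <- NA            # column 2: 80% missing
  X[1, 1] <- NA              # rows: at most 2/3... row 1 has 2 of 3
  tb <- make_cohort(X)
  out <- complete_matrix(tb)
  expect_identical(out$report$dropped_biomarkers[1], "bm02")
})

test_that("iterative exclusion matches a brute-force oracle on MCAR data", {
  set.seed(7)
  X <- matrix(rnorm(200 * 20), 200, 20)
  X[sample(length(X), 0.05 * length(X))] <- NA
  tb <- make_cohort(X)
  out <- complete_matrix(tb)
  oracle <- brute_force_complete(X)
  expect_identical(out$table$participant_id,
                   tb$participant_id[oracle$rows])
  expect_identical(biomarker_names(out$table),
                   sprintf("bm%02d", oracle$cols))
  expect_false(anyNA(out$table))
})

test_that("complete_matrix fails loudly when everything is missing", {
  X <- matrix(NA_real_, 3, 2)
  expect_error(complete_matrix(make_cohort(X)), "everything removed")
})

test_that("drop_redundant keeps the earlier column of a redundant pair", {
  # exact duplicate
  X <- exact_corr_data(100, diag(3), seed = 2)
  tb <- make_cohort(cbind(X, bm04 = X[, 1]))
  out <- drop_redundant(tb)
  expect_identical(out$report$dropped_biomarkers, "bm04")
  # independent columns untouched
  out2 <- drop_redundant(make_cohort(X))
  expect_length(out2$report$dropped_biomarkers, 0)
  expect_error(drop_redundant(make_cohort(X), threshold = 0), "threshold")
})

test_that("redundancy chain A~B(.95) B~C(.95) A~C(.85) keeps A and C", {
  R <- matrix(c(1, .95, .85, .95, 1, .95, .85, .95, 1), 3)
  X <- exact_corr_data(200, R, seed = 3)
  out <- drop_redundant(make_cohort(X))
  expect_identical(out$report$dropped_biomarkers, "bm02")
  expect_identical(biomarker_names(out$table), c("bm01", "bm03"))
})

test_that("gaussianize picks the skewness-minimizing transform", {
  set.seed(11)
  n <- 4000
  tb <- make_cohort(cbind(
    normal = rnorm(n),
    lognorm = rlnorm(n, 0, 1),
    leftskew = log(abs(rnorm(n, 8, 1)))
  ))
  out <- gaussianize(tb)
  choice <- out$report$transform_per_biomarker
  expect_identical(unname(choice["normal"]), "identity")
  expect_identical(unname(choice["lognorm"]), "log")
  # oracle: each choice attains the minimal |weighted skewness| among the
  # three candidates computed directly
  expect_identical(unname(choice["leftskew"]), "exp")
  for (b in names(choice)) {
    x <- tb[[b]]; w <- tb$weight
    m <- weighted_mean(x, w)
    shift <- if (min(x) > 0) 0 else -min(x) + 1e-6 * diff(range(x))
    sk <- c(identity = abs(weighted_skewness(x, w)),
            log = abs(weighted_skewness(log(x + shift), w)),
            exp = abs(weighted_skewness(exp(x - m), w)))
    expect_identical(unname(choice[b]), names(which.min(sk)))
  }
})

test_that("weighted standardization matches direct formulas and is
           replication-invariant", {
  set.seed(4)
  X <- matrix(rnorm(10 * 2, mean = 3, sd = 2), 10, 2)
  w <- runif(10, 0.5, 3)
  tb <- make_cohort(X, weight = w)
  out <- weighted_standardize(tb)
  for (b in biomarker_names(tb)) {
    expect_lt(abs(weighted_mean(out$table[[b]], w)), 1e-10)
    expect_lt(abs(weighted_var(out$table[[b]], w) - 1), 1e-10)
    # formula oracle for the recorded moments
    expect_equal(out$report$weighted_means[[b]],
                 sum(w / sum(w) * tb[[b]]))
  }
  # equal weights reduce to classical (population) z-scoring
  tb_eq <- make_cohort(X)
  z <- weighted_standardize(tb_eq)$table
  for (k in 1:2) {
    cls <- (X[, k] - mean(X[, k])) / (sd(X[, k]) * sqrt(9 / 10))
    expect_equal(z[[k + 5]], cls, tolerance = 1e-12)
  }
  # duplicating a row and halving its weight changes nothing
  tb2 <- rbind(tb, tb[1, ])
  tb2$weight[c(1, 11)] <- tb$weight[1] / 2
  out2 <- weighted_standardize(tb2)
  expect_equal(out2$report$weighted_means, out$report$weighted_means)
  expect_equal(out2$report$weighted_sds, out$report$weighted_sds)
  # positive rescaling of all weights changes nothing
  tb3 <- tb; tb3$weight <- tb$weight * 17
  out3 <- weighted_standardize(tb3)
  expect_equal(out3$table[biomarker_names(tb3)],
               out$table[biomarker_names(tb)])
})

test_that("the preprocessing pipeline is idempotent", {
  cfg <- synth_config(n_participants = 800, n_biomarkers = 4, seed = 19)
  p1 <- preprocess(generate_cohort(cfg))
  p2 <- preprocess(p1$table)
  expect_length(p2$reports$complete_matrix$dropped_samples, 0)
  expect_length(p2$reports$drop_redundant$dropped_biomarkers, 0)
  for (b in biomarker_names(p1$table)) {
    expect_equal(p2$table[[b]], p1$table[[b]], tolerance = 1e-8)
  }
})

test_that("biomarker-age association recovers exact and planted signals", {
  set.seed(6)
  n <- 20000
  age <- sample(20:79, n, replace = TRUE)
  az <- (age - mean(age)) / sd(age)
  X <- cbind(
    agecopy = as.numeric(age),
    indep = rnorm(n),
    planted = 0.3 * az + sqrt(1 - 0.09) * rnorm(n)
  )
  tb <- make_cohort(X, age = age)
  tb <- weighted_standardize(tb)$table
  res <- biomarker_age_association(tb)
  expect_equal(res$r[res$biomarker == "agecopy"], 1, tolerance = 1e-10)
  expect_equal(res$neg_log_corrected_p[res$biomarker == "agecopy"], 308)
  expect_gt(res$corrected_p[res$biomarker == "indep"], 0.5)
  expect_lt(abs(res$r[res$biomarker == "planted"] - 0.3), 0.02)
  # display convention: slope_x100 is 100 times the sd/sd-year slope
  expect_equal(res$slope_x100, 100 * res$slope)
  expect_error(biomarker_age_association(make_cohort(X[1:10, ],
                                                     age = rep(50, 10))),
               "distinct ages")
})
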