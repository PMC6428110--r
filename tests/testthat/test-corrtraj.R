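# Weighted Pearson correlation, bootstrap series, meta-regression and
# the six-class trajectory taxonomy.

test_that("weighted Pearson matches the direct formula and classical cor", {
  x <- c(0, 1, 2, 3); y <- c(0, 1, 2, 10); w <- rep(1, 4)
  expect_equal(weighted_pearson(x, y, w), cor(x, y), tolerance = 1e-12)
  expect_equal(weighted_pearson(x, x, runif(4, 1, 3)), 1)
  expect_equal(weighted_pearson(x, -x, runif(4, 1, 3)), -1)
  expect_error(weighted_pearson(rep(1, 5), rnorm(5), rep(1, 5)), "constant")
  expect_error(weighted_pearson(1:3, 1:4, rep(1, 4)), "equal lengths")
  # property: equal weights reduce to classical Pearson
  set.seed(2)
  for (k in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    expect_equal(weighted_pearson(a, b, rep(2, 30)), cor(a, b),
                 tolerance = 1e-12)
  }
})

test_that("per-bin correlation matrices are symmetric with unit diagonal", {
  set.seed(3)
  X <- matrix(rnorm(200 * 4), 200, 4)
  w <- rlnorm(200, 0, 0.5)
  R <- weighted_corr_matrix(X, w)
  expect_equal(R, t(R))
  expect_equal(diag(R), rep(1, 4))
  expect_true(all(abs(R) <= 1))
})

test_that("bootstrap SE approaches the Fisher large-sample value", {
  set.seed(5)
  n <- 400
  tb <- make_cohort(matrix(rnorm(n * 2), n, 2), age = rep(50L, n))
  series <- bootstrap_corr_series(tb, c("bm01", "bm02"), B = 400, seed = 9)
  fisher <- 1 / sqrt(n - 3)
  expect_lt(abs(series$se - fisher) / fisher, 0.25)
  # determinism
  series2 <- bootstrap_corr_series(tb, c("bm01", "bm02"), B = 400, seed = 9)
  expect_identical(series, series2)
})

test_that("bins below the minimum size are skipped with a warning", {
  set.seed(6)
  age <- c(rep(40L, 150), rep(41L, 30))
  tb <- make_cohort(matrix(rnorm(180 * 2), 180, 2), age = age)
  expect_warning(
    s <- bootstrap_corr_series(tb, c("bm01", "bm02"), B = 50, seed = 1,
                               min_n = 100),
    "skipping"
  )
  expect_identical(s$age, 40L)
})

test_that("meta-regression reproduces an exact line to machine precision", {
  ages <- 20:79
  series <- data.frame(age = ages, estimate = 0.5 - 0.01 * (ages - 20),
                       se = rep(0.05, 60))
  fit <- meta_regress(series, family_size = 1)
  expect_equal(fit$slope, -0.01, tolerance = 1e-12)
  expect_equal(fit$start_value, 0.5, tolerance = 1e-12)
  expect_equal(fit$end_value, 0.5 - 0.59, tolerance = 1e-12)
  expect_identical(fit$class, "dec_pn")
})

test_that("meta-regression on a constant series finds no trend", {
  series <- data.frame(age = 20:79, estimate = rep(0.3, 60),
                       se = rep(0.05, 60))
  fit <- meta_regress(series, family_size = 10)
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_identical(fit$class, "none")
  expect_error(meta_regress(series[1:2, ]), "3 age bins")
  expect_error(meta_regress(transform(series, se = 0)), "zero")
})

test_that("heteroskedastic WLS matches the normal-equation oracle", {
  set.seed(8)
  ages <- 20:49
  se <- runif(30, 0.02, 0.2)
  est <- 0.2 - 0.004 * (ages - 20) + rnorm(30, 0, se)
  fit <- meta_regress(data.frame(age = ages, estimate = est, se = se),
                      family_size = 3)
  W <- diag(1 / se^2)
  X <- cbind(1, ages)
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% est)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  # slope SE: known-variance value times the estimated residual
  # dispersion (floored at 1), as a weighted lm would report
  Q <- sum((est - X %*% beta)^2 / se^2)
  scale2 <- max(1, Q / (length(ages) - 2))
  expect_equal(fit$slope_se, sqrt(solve(XtWX)[2, 2] * scale2),
               tolerance = 1e-10)
  expect_equal(fit$p,
               2 * pt(-abs(fit$slope / fit$slope_se), length(ages) - 2),
               tolerance = 1e-12)
  expect_equal(fit$corrected_p, fit$p * 3, tolerance = 1e-12)
})

test_that("the six-class taxonomy covers all sign patterns", {
  # the replicated height-vs-SBP shape: 0.39 at 20, -0.28 at 80
  expect_identical(classify_trajectory(-0.011, 0.39, -0.28, 1e-10),
                   "dec_pn")
  expect_identical(classify_trajectory(0.003, 0.1, 0.3, 1e-4), "inc_pp")
  expect_identical(classify_trajectory(-0.011, 0.39, -0.28, 0.2), "none")
  expect_identical(classify_trajectory(-0.002, 0.5, 0.2, 0.01), "dec_pp")
  expect_identical(classify_trajectory(-0.002, -0.1, -0.3, 0.01), "dec_nn")
  expect_identical(classify_trajectory(0.002, -0.3, -0.1, 0.01), "inc_nn")
  expect_identical(classify_trajectory(0.005, -0.1, 0.2, 0.01), "inc_np")
  # exact zero endpoints break toward the non-switching class
  expect_identical(classify_trajectory(-0.002, 0.12, 0, 0.01), "dec_pp")
  expect_identical(classify_trajectory(0.002, 0, 0.12, 0.01), "inc_pp")
})

test_that("a planted sign-switching pair is recovered as dec_pn", {
  plan <- data.frame(i = 1, j = 2, intercept = 0.4, slope = -0.7 / 59)
  cfg <- synth_config(n_participants = 24000, n_biomarkers = 3,
                      correlation_plan = plan, seed = 31)
  pp <- preprocess(generate_cohort(cfg))$table
  ct <- corr_trajectories(pp, B = 60, seed = 13, min_n = 100)
  fit <- ct$fits[ct$fits$pair == "bm01~bm02", ]
  expect_identical(fit$class, "dec_pn")
  expect_lt(abs(fit$slope - (-0.7 / 59)), 2 * fit$slope_se)
})

test_that("mean |r| trend recovers a planted decline", {
  # five disjoint declining pairs (near-independent estimates, so the
  # SD-based bin SE is honest); the panel mean declines at 5/45 the rate
  p <- 10
  plan <- data.frame(i = c(1, 3, 5, 7, 9), j = c(2, 4, 6, 8, 10),
                     intercept = 0.45, slope = -1e-3)
  cfg <- synth_config(n_participants = 15000, n_biomarkers = p,
                      correlation_plan = plan, seed = 17)
  pp <- preprocess(generate_cohort(cfg))$table
  panel <- corr_panel_series(pp, B = 40, seed = 23, min_n = 100)
  trend <- mean_abs_corr_trend(panel)
  expect_lt(abs(trend$fit$slope - (-1e-3 * 5 / 45)),
            2 * trend$fit$slope_se)
  expect_error(mean_abs_corr_trend(panel, fits = NULL,
                                   restrict_to_significant = TRUE),
               "fits required")
  # restriction to an empty significant set errors
  fits0 <- data.frame(class = rep("none", nrow(panel$pairs)))
  expect_error(mean_abs_corr_trend(panel, fits = fits0,
                                   restrict_to_significant = TRUE),
               "no significant pairs")
})
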