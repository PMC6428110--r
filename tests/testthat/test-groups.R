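# Demographic contrasts: baseline and trajectory differences, and
# random-split control groups as the negative control.

test_that("control groups split into halves deterministically", {
  tb10 <- make_cohort(matrix(rnorm(20), 10, 2))
  g <- make_control_groups(tb10, seed = 1)
  expect_equal(sort(unname(vapply(g, nrow, integer(1)))), c(5L, 5L))
  tb11 <- make_cohort(matrix(rnorm(22), 11, 2))
  g11 <- make_control_groups(tb11, seed = 1)
  expect_equal(sort(unname(vapply(g11, nrow, integer(1)))), c(5L, 6L))
  expect_identical(make_control_groups(tb11, seed = 1), g11)
  expect_setequal(c(g11[[1]]$participant_id, g11[[2]]$participant_id),
                  tb11$participant_id)
  expect_error(make_control_groups(tb10[1, ], seed = 1), "at least 2")
})

test_that("swapping the groups flips differences and keeps p-values", {
  plan <- data.frame(i = 1, j = 2, intercept = 0.2, slope = 0)
  gp <- data.frame(variable = "sex", level = "female", i = 1, j = 2,
                   d_intercept = 0.2, d_slope = 0)
  cfg <- synth_config(n_participants = 4000, n_biomarkers = 3,
                      correlation_plan = plan, group_plan = gp, seed = 61)
  pp <- preprocess(generate_cohort(cfg))$table
  ab <- baseline_difference(pp, by = "sex", quantity = "correlation",
                            B = 100, seed = 2,
                            levels = c("female", "male"))
  ba <- baseline_difference(pp, by = "sex", quantity = "correlation",
                            B = 100, seed = 2,
                            levels = c("male", "female"))
  expect_equal(ab$diff, -ba$diff, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$corrected_p, ab$p * nrow(ab), tolerance = 1e-12)
})

test_that("a planted baseline correlation difference is detected", {
  plan <- data.frame(i = 1, j = 2, intercept = 0.04, slope = 0)
  gp <- data.frame(variable = "sex", level = "female", i = 1, j = 2,
                   d_intercept = 0.28, d_slope = 0)
  cfg <- synth_config(n_participants = 10000, n_biomarkers = 4,
                      correlation_plan = plan, group_plan = gp, seed = 62)
  pp <- preprocess(generate_cohort(cfg))$table
  bd <- baseline_difference(pp, by = "sex", quantity = "correlation",
                            B = 200, seed = 3,
                            levels = c("female", "male"))
  hit <- bd[bd$id == "bm01~bm02", ]
  expect_true(hit$significant)
  expect_gt(hit$diff, 0.15)
  expect_error(baseline_difference(pp[pp$sex == "female", ], by = "sex"),
               "empty group")
})

test_that("identically generated groups produce no baseline findings", {
  cfg <- synth_config(n_participants = 8000, n_biomarkers = 6, seed = 63)
  pp <- preprocess(generate_cohort(cfg))$table
  bd <- baseline_difference(pp, by = "control", quantity = "correlation",
                            B = 150, seed = 4)
  expect_lte(sum(bd$significant), 1)
})

test_that("baseline r2 differences run end to end on a null contrast", {
  cfg <- synth_config(n_participants = 1200, n_biomarkers = 4, seed = 64)
  plan <- data.frame(i = c(1, 2), j = c(4, 4), intercept = 0.5, slope = 0)
  cfg$correlation_plan <- plan
  pp <- preprocess(generate_cohort(cfg))$table
  bd <- baseline_difference(pp, by = "control", quantity = "r2",
                            B = 50, seed = 5,
                            config = predict_config(boot_B = 50,
                                                    cv_folds = 5))
  expect_equal(nrow(bd), 4)
  expect_equal(sum(bd$significant), 0)
  expect_equal(bd$corrected_p, bd$p * 4, tolerance = 1e-12)
})

test_that("a planted trajectory difference between sexes is recovered", {
  plan <- data.frame(i = 1, j = 2, intercept = 0.45, slope = -0.008)
  gp <- data.frame(variable = "sex", level = "male", i = 1, j = 2,
                   d_intercept = -0.25, d_slope = 0.008)  # males flat at 0.2
  cfg <- synth_config(n_participants = 30000, n_biomarkers = 4,
                      correlation_plan = plan, group_plan = gp, seed = 65)
  pp <- preprocess(generate_cohort(cfg))$table
  td <- trajectory_difference(pp, by = "sex", B = 60, seed = 6,
                              min_n = 80, levels = c("female", "male"))
  hit <- td[td$pair == "bm01~bm02", ]
  expect_true(hit$significant)
  expect_lt(abs(hit$slope - (-0.008)), 3 * hit$slope_se)
  # and identical trajectories yield no finding on the other pairs
  expect_equal(sum(td$significant[td$pair != "bm01~bm02"]), 0)
})

test_that("trajectory differences refuse a too-short common bin grid", {
  set.seed(66)
  age <- rep(c(30L, 31L), each = 200)
  tb <- make_cohort(matrix(rnorm(400 * 3), 400, 3), age = age,
                    sex = sample(c("female", "male"), 400, TRUE))
  expect_error(trajectory_difference(tb, by = "sex", B = 20, seed = 1,
                                     min_n = 50),
               "common age bins")
})

test_that("generic series comparison matches meta_regress on differences", {
  a <- data.frame(age = c(25, 45, 65), estimate = c(0.5, 0.4, 0.3),
                  se = c(0.05, 0.05, 0.05))
  b <- data.frame(age = c(25, 45, 65), estimate = c(0.3, 0.3, 0.3),
                  se = c(0.05, 0.05, 0.05))
  cmp <- compare_series(a, b, family_size = 50)
  direct <- meta_regress(
    data.frame(age = a$age, estimate = a$estimate - b$estimate,
               se = sqrt(a$se^2 + b$se^2)), 50)
  expect_equal(cmp$slope, direct$slope)
  expect_equal(cmp$corrected_p, direct$p * 50)
})
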