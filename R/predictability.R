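# Cross-fitted elastic-net predictability: how well each biomarker is
# predicted from all the others, per age window with equalized sample
# sizes, with bootstrap R^2 standard errors and trajectory tests.

#' Elastic-net configuration
#'
#' @param alpha_mixing elastic-net mixing parameter (1 = lasso, 0 =
#'   ridge).
#' @param n_lambda number of penalty values on the geometric path.
#' @param lambda_min_ratio smallest penalty as a fraction of the
#'   data-driven maximum.
#' @param cv_folds cross-validation folds for penalty selection.
#' @param boot_B bootstrap replicates for the R^2 standard error.
#' @param weighted_loss use survey weights as case weights in the
#'   elastic-net loss (default: unweighted loss on the already
#'   weight-standardized matrix).
#' @return a list of class `predict_config`.
#' @export
predict_config <- function(alpha_mixing = 0.5, n_lambda = 100L,
                           lambda_min_ratio = 1e-4, cv_folds = 10L,
                           boot_B = 1000L, weighted_loss = FALSE) {
  stopifnot(alpha_mixing >= 0, alpha_mixing <= 1, n_lambda >= 2,
            cv_folds >= 3, boot_B >= 1)
  structure(
    list(alpha_mixing = alpha_mixing, n_lambda = n_lambda,
         lambda_min_ratio = lambda_min_ratio, cv_folds = cv_folds,
         boot_B = boot_B, weighted_loss = weighted_loss),
    class = "predict_config"
  )
}

# Non-overlapping window labels tiling [lo, hi) by window_years.
window_breaks <- function(lo = 20L, hi = 80L, window_years = 1L) {
  starts <- seq.int(lo, hi - 1L, by = window_years)
  data.frame(
    lo = starts,
    hi = pmin(starts + window_years, hi),
    label = sprintf("[%d,%d)", starts, pmin(starts + window_years, hi)),
    mid = (starts + pmin(starts + window_years, hi)) / 2
  )
}

#' Equalize sample sizes across age windows
#'
#' Tiles the age range with non-overlapping windows of `window_years`
#' and reduces every window to exactly `samples_per_window` rows by
#' seeded uniform subsampling without replacement. Comparing model
#' performance across windows of unequal size would bias the trajectory
#' (larger windows train better models), so the quota is enforced
#' strictly.
#'
#' @param table preprocessed cohort data.frame.
#' @param window_years window width in years.
#' @param samples_per_window quota per window, or `"auto"` for the
#'   smallest window count.
#' @param seed integer seed.
#' @param age_range integer `c(lo, hi)` range to tile.
#' @return named list of window data.frames, each with attributes
#'   `window` (label) and `mid` (window midpoint age).
#' @export
equalize_windows <- function(table, window_years = 1L,
                             samples_per_window = "auto", seed = 1L,
                             age_range = c(20L, 80L)) {
  wins <- window_breaks(age_range[1], age_range[2], window_years)
  rows_per <- lapply(seq_len(nrow(wins)), function(k) {
    which(table$age >= wins$lo[k] & table$age < wins$hi[k])
  })
  sizes <- lengths(rows_per)
  if (identical(samples_per_window, "auto")) {
    samples_per_window <- min(sizes)
  }
  if (any(sizes < samples_per_window)) {
    bad <- wins$label[sizes < samples_per_window]
    stop("windows below the quota of ", samples_per_window, ": ",
         paste(bad, collapse = ", "))
  }
  out <- vector("list", nrow(wins))
  names(out) <- wins$label
  for (k in seq_len(nrow(wins))) {
    set.seed(child_seed(seed, paste0("window", wins$label[k])))
    keep <- sample(rows_per[[k]], samples_per_window)
    sub <- table[sort(keep), , drop = FALSE]
    rownames(sub) <- NULL
    attr(sub, "window") <- wins$label[k]
    attr(sub, "mid") <- wins$mid[k]
    out[[k]] <- sub
  }
  out
}

# Shared penalty-path CV fit. Returns the cv.glmnet object.
cv_enet <- function(X, y, config, weights = NULL, foldid_seed = NULL) {
  if (stats::var(y) == 0) stop("constant target: degenerate fit")
  if (!is.null(foldid_seed)) set.seed(foldid_seed)
  args <- list(
    x = X, y = y, alpha = config$alpha_mixing,
    nlambda = config$n_lambda, lambda.min.ratio = config$lambda_min_ratio,
    nfolds = config$cv_folds, family = "gaussian",
    type.measure = "mse"
  )
  if (!is.null(weights)) args$weights <- weights
  do.call(glmnet::cv.glmnet, args)
}

#' Cross-fitted out-of-sample R^2 for one target biomarker
#'
#' The window is split 50/50; an elastic net (penalty selected by
#' `cv_folds`-fold CV minimizing MSE over an `n_lambda`-point geometric
#' path) is fit on one half and predicts the other, the halves are
#' swapped, and all held-out predictions are scored together with the
#' uncorrected coefficient of determination
#' `R^2 = 1 - SSE / SST` (SST about the held-out sample mean). Negative
#' values are possible — the model then predicts worse than the mean —
#' and are reported as-is. The standard error comes from `boot_B`
#' resamples of the (prediction, observation) pairs.
#'
#' @param window_table one window data.frame (from [equalize_windows()]
#'   or any complete standardized cohort table with >= 60 rows).
#' @param target biomarker name to predict from all the others.
#' @param config a [predict_config()].
#' @param seed integer seed (split, CV folds, bootstrap).
#' @return one-row data.frame: target, window, mid, r2, r2_se, n_used.
#' @export
cross_fit_r2 <- function(window_table, target, config = predict_config(),
                         seed = 1L) {
  bms <- biomarker_names(window_table)
  stopifnot(target %in% bms)
  n <- nrow(window_table)
  if (n < 60) stop("need at least 60 rows for a 50/50 cross-fit")
  X <- as.matrix(window_table[, setdiff(bms, target), drop = FALSE])
  y <- window_table[[target]]
  w <- if (config$weighted_loss) window_table$weight else NULL

  set.seed(child_seed(seed, paste0("split", target)))
  half_a <- sample.int(n, floor(n / 2))
  half_b <- setdiff(seq_len(n), half_a)
  pred <- numeric(n)
  for (halves in list(c(1, 2), c(2, 1))) {
    tr <- if (halves[1] == 1) half_a else half_b
    te <- if (halves[1] == 1) half_b else half_a
    fit <- cv_enet(X[tr, , drop = FALSE], y[tr], config,
                   weights = w[tr],
                   foldid_seed = child_seed(seed,
                                            paste0("cv", target, halves[1])))
    pred[te] <- as.numeric(stats::predict(fit, X[te, , drop = FALSE],
                                          s = "lambda.min"))
  }
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst

  set.seed(child_seed(seed, paste0("r2boot", target)))
  boot <- vapply(seq_len(config$boot_B), function(b) {
    idx <- sample.int(n, replace = TRUE)
    yb <- y[idx]; pb <- pred[idx]
    1 - sum((yb - pb)^2) / sum((yb - mean(yb))^2)
  }, numeric(1))

  data.frame(
    target = target,
    window = attr(window_table, "window") %||% "all",
    mid = attr(window_table, "mid") %||% mean(window_table$age),
    r2 = r2, r2_se = stats::sd(boot), n_used = n,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predictability records for all targets across all windows
#'
#' @param windows list of window data.frames (from [equalize_windows()]).
#' @param config a [predict_config()].
#' @param seed integer seed.
#' @param targets biomarker names to predict (default: all).
#' @return data.frame of [cross_fit_r2()] rows.
#' @export
predictability_records <- function(windows, config = predict_config(),
                                   seed = 1L, targets = NULL) {
  if (is.null(targets)) targets <- biomarker_names(windows[[1]])
  out <- list()
  for (k in seq_along(windows)) {
    for (tg in targets) {
      out[[length(out) + 1L]] <-
        cross_fit_r2(windows[[k]], tg, config,
                     seed = child_seed(seed, paste0("win", k)))
    }
  }
  do.call(rbind, out)
}

#' Age trajectory of one biomarker's predictability
#'
#' Meta-regression of the per-window R^2 on the window midpoint age,
#' weighting by inverse bootstrap variance and Bonferroni-correcting
#' over the number of biomarkers. Classification is restricted to
#' increase / decrease / none.
#'
#' @param records rows of [cross_fit_r2()] for one target (>= 3
#'   windows).
#' @param family_size Bonferroni family size (number of biomarkers).
#' @return one-row data.frame with the meta-regression fields and
#'   `class` in `c("increase", "decrease", "none")`.
#' @export
predictability_trajectory <- function(records, family_size) {
  if (nrow(records) < 3) stop("need at least 3 windows")
  fit <- meta_regress(
    data.frame(age = records$mid, estimate = records$r2,
               se = records$r2_se),
    family_size = family_size
  )
  fit$class <- if (fit$corrected_p >= 0.05) "none"
               else if (fit$slope < 0) "decrease" else "increase"
  fit
}

#' Trend in the mean predictability with age
#'
#' Per window, the mean R^2 across targets is meta-regressed on the
#' window midpoint with SE = SD / sqrt(number of targets).
#'
#' @param records data.frame of [cross_fit_r2()] rows for all targets.
#' @param restrict_to optional character vector of targets to keep (e.g.
#'   those with significant individual trajectories).
#' @return list with `series` and `fit` as in [mean_abs_corr_trend()].
#' @export
mean_predictability_trend <- function(records, restrict_to = NULL) {
  if (!is.null(restrict_to)) {
    if (length(restrict_to) == 0) stop("empty restriction set")
    records <- records[records$target %in% restrict_to, , drop = FALSE]
    if (nrow(records) == 0) stop("empty restriction set")
  }
  mids <- sort(unique(records$mid))
  series <- do.call(rbind, lapply(mids, function(m) {
    r <- records$r2[records$mid == m]
    data.frame(age = m, estimate = mean(r), sd = stats::sd(r),
               se = stats::sd(r) / sqrt(length(r)), n_targets = length(r))
  }))
  list(series = series, fit = meta_regress(series, family_size = 1L))
}
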