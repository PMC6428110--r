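# Per-window elastic-net regression coefficients on the full window (no
# train/test split), parametric-bootstrap uncertainty, and age-trajectory
# tests with the six-class taxonomy.

#' Elastic-net coefficients on a full window
#'
#' Fits the elastic net on all rows of the window (penalty selected by
#' cross-validation, same protocol as [cross_fit_r2()] but without
#' splitting) and records every predictor's coefficient at the selected
#' penalty. `selected` flags the nonzero coefficients.
#'
#' @param window_table one window data.frame.
#' @param target biomarker to predict from all others.
#' @param config a [predict_config()].
#' @param seed integer seed (CV folds).
#' @return list with `records` (data.frame: target, predictor, window,
#'   mid, coefficient, selected), `lambda` (selected penalty), `fitted`,
#'   `residual_sd`, and the fitted `glmnet` inputs needed for the
#'   parametric bootstrap.
#' @export
fit_full_coefficients <- function(window_table, target,
                                  config = predict_config(), seed = 1L) {
  bms <- biomarker_names(window_table)
  stopifnot(target %in% bms)
  preds <- setdiff(bms, target)
  X <- as.matrix(window_table[, preds, drop = FALSE])
  y <- window_table[[target]]
  w <- if (config$weighted_loss) window_table$weight else NULL
  cv <- cv_enet(X, y, config, weights = w,
                foldid_seed = child_seed(seed, paste0("cvfull", target)))
  lam <- cv$lambda.min
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1L]
  fitted <- as.numeric(stats::predict(cv, X, s = "lambda.min"))
  records <- data.frame(
    target = target, predictor = preds,
    window = attr(window_table, "window") %||% "all",
    mid = attr(window_table, "mid") %||% mean(window_table$age),
    coefficient = beta, selected = beta != 0,
    stringsAsFactors = FALSE
  )
  list(records = records, lambda = lam, alpha = config$alpha_mixing,
       X = X, y = y, weights = w, fitted = fitted,
       residual_sd = stats::sd(y - fitted))
}

#' Parametric-bootstrap standard errors of elastic-net coefficients
#'
#' Simulates `y* = fitted + N(0, residual_sd)` and refits the elastic
#' net `B` times at the same (CV-selected, then fixed) penalty; the SE of
#' each coefficient is its standard deviation across refits. Holding the
#' penalty fixed isolates coefficient variability from tuning
#' variability.
#'
#' @param fit result of [fit_full_coefficients()].
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @return the `records` data.frame of `fit` with columns `se` and
#'   `times_selected` added.
#' @export
parametric_bootstrap_se <- function(fit, B = 100L, seed = 1L) {
  n <- length(fit$y)
  p <- ncol(fit$X)
  if (fit$residual_sd < 1e-12) {
    warning("zero residual variance: all coefficient SEs are 0")
    fit$records$se <- 0
    fit$records$times_selected <- B
    return(fit$records)
  }
  set.seed(child_seed(seed, "parboot"))
  betas <- matrix(NA_real_, B, p)
  for (b in seq_len(B)) {
    ystar <- fit$fitted + stats::rnorm(n, 0, fit$residual_sd)
    gb <- glmnet::glmnet(fit$X, ystar, alpha = fit$alpha,
                         lambda = fit$lambda, weights = fit$weights)
    betas[b, ] <- as.numeric(gb$beta)
  }
  fit$records$se <- apply(betas, 2, stats::sd)
  fit$records$times_selected <- colSums(betas != 0)
  fit$records
}

#' Coefficient records with SEs for all targets across windows
#'
#' @param windows list of window data.frames.
#' @param config a [predict_config()].
#' @param B parametric-bootstrap replicates per fit.
#' @param seed integer seed.
#' @param targets biomarker names (default: all).
#' @return data.frame of coefficient records (target, predictor, window,
#'   mid, coefficient, selected, se, times_selected).
#' @export
coefficient_records <- function(windows, config = predict_config(),
                                B = 100L, seed = 1L, targets = NULL) {
  if (is.null(targets)) targets <- biomarker_names(windows[[1]])
  out <- list()
  for (k in seq_along(windows)) {
    for (tg in targets) {
      fit <- fit_full_coefficients(windows[[k]], tg, config,
                                   seed = child_seed(seed, paste0("cw", k)))
      out[[length(out) + 1L]] <-
        parametric_bootstrap_se(fit, B = B,
                                seed = child_seed(seed,
                                                  paste0("cb", k, tg)))
    }
  }
  do.call(rbind, out)
}

#' Age trajectory of one regression coefficient
#'
#' Meta-regression of a (target, predictor) coefficient on the window
#' midpoint age, Bonferroni-corrected over the number of ordered
#' (target, predictor) pairs, with the full six-class taxonomy of
#' [classify_trajectory()]. Windows where the bootstrap SE is zero (the
#' predictor was never selected) carry no information and are dropped;
#' a coefficient that is zero in every window is classified `none`.
#'
#' @param records coefficient records for one (target, predictor) pair
#'   across windows (>= 3 windows with positive SE).
#' @param family_size Bonferroni family size (number of biomarkers times
#'   number of biomarkers minus one).
#' @return one-row data.frame of trajectory-fit fields.
#' @export
coefficient_trajectory <- function(records, family_size) {
  if (nrow(records) < 3) stop("need at least 3 windows")
  if (all(records$coefficient == 0)) {
    out <- data.frame(slope = 0, slope_se = NA_real_, intercept = 0,
                      z = NA_real_, p = 1, corrected_p = family_size,
                      neg_log_corrected_p = -log10(family_size),
                      start_value = 0, end_value = 0, class = "none",
                      stringsAsFactors = FALSE)
    return(out)
  }
  keep <- records$se > 0
  if (sum(keep) < 3) stop("fewer than 3 windows with positive SE")
  meta_regress(
    data.frame(age = records$mid[keep],
               estimate = records$coefficient[keep],
               se = records$se[keep]),
    family_size = family_size
  )
}
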