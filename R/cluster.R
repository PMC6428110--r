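# Weighted hierarchical clustering of biomarkers on 1 - mean correlation,
# with partial-correlation adjustment for demographics and bootstrap /
# multiscale-bootstrap cluster support (BP and AU values).

#' Residualize biomarkers on demographic covariates
#'
#' Replaces each biomarker by its residual from a survey-weighted linear
#' regression on age and indicator columns for the categorical
#' covariates, then re-standardizes the residuals to weighted mean 0 and
#' variance 1. Correlations of the adjusted table are partial
#' correlations given the covariates.
#'
#' @param table preprocessed cohort data.frame.
#' @param covariates subset of `c("age", "sex", "ethnicity")`.
#' @return the adjusted cohort data.frame.
#' @export
partial_adjust <- function(table, covariates = c("age", "sex", "ethnicity")) {
  stopifnot(all(covariates %in% c("age", "sex", "ethnicity")))
  for (cv in setdiff(covariates, "age")) {
    if (length(unique(table[[cv]])) < 2) {
      stop("collinear covariates: ", cv, " has a single level")
    }
  }
  form <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  X <- stats::model.matrix(form, data = table)
  if (qr(X)$rank < ncol(X)) stop("collinear covariates")
  bms <- biomarker_names(table)
  Y <- as.matrix(table[, bms, drop = FALSE])
  fit <- stats::lm.wfit(X, Y, table$weight)
  res <- as.matrix(fit$residuals)
  for (k in seq_along(bms)) {
    v <- weighted_var(res[, k], table$weight)
    if (v <= 0) stop("biomarker ", bms[k], " fully explained by covariates")
    table[[bms[k]]] <-
      (res[, k] - weighted_mean(res[, k], table$weight)) / sqrt(v)
  }
  table
}

# Member sets (alphabetically sorted label vectors) of every internal
# node of an hclust tree, indexed by merge order.
hclust_member_sets <- function(hc) {
  p <- nrow(hc$merge) + 1L
  labels <- if (is.null(hc$labels)) as.character(seq_len(p)) else hc$labels
  sets <- vector("list", p - 1L)
  for (k in seq_len(p - 1L)) {
    members <- integer(0)
    for (m in hc$merge[k, ]) {
      members <- c(members, if (m < 0) -m else sets[[m]])
    }
    sets[[k]] <- members
  }
  lapply(sets, function(ix) sort(labels[ix]))
}

#' Average-linkage clustering of biomarkers on 1 - correlation
#'
#' Agglomerative average-linkage clustering with distance
#' `D = 1 - r` (survey-weighted correlation), so the height of each merge
#' is one minus the mean pairwise correlation between the two merged
#' clusters: perfectly correlated biomarkers merge at height 0,
#' uncorrelated ones at height 1.
#'
#' @param R correlation matrix (e.g. from [weighted_corr_matrix()]).
#' @return list with `hclust` (the stats::hclust object) and `nodes`
#'   (data.frame: node, rank = merge order, height, n_members, members as
#'   a "+"-joined string).
#' @export
weighted_hclust <- function(R) {
  if (nrow(R) < 2) stop("need at least 2 biomarkers to cluster")
  hc <- stats::hclust(stats::as.dist(1 - R), method = "average")
  sets <- hclust_member_sets(hc)
  nodes <- data.frame(
    node = seq_along(sets),
    rank = seq_along(sets),
    height = hc$height,
    n_members = lengths(sets),
    members = vapply(sets, paste, character(1), collapse = "+"),
    stringsAsFactors = FALSE
  )
  list(hclust = hc, nodes = nodes)
}

#' Bootstrap and multiscale-bootstrap cluster support
#'
#' BP (bootstrap probability) of a cluster is the percentage of bootstrap
#' dendrograms — rows resampled with replacement, weights carried —
#' containing exactly the same member set. The AU (approximately
#' unbiased) value corrects BP by multiscale bootstrap: bootstraps are
#' drawn at sizes `ceil(rho * n)` for each scale `rho`, the normal
#' quantile `z(rho) = qnorm(1 - BP_rho)` is fitted as
#' `z = v * sqrt(rho) + c / sqrt(rho)` by weighted least squares, and
#' `AU = 100 * (1 - pnorm(v - c))`. When the curvature term `c` is zero,
#' AU equals BP at scale 1. Degenerate BP values of 0 or 1 are clamped to
#' `1/(2B)` from the boundary. A cluster is flagged significant when
#' AU > 95 (alpha = 0.95).
#'
#' @param table preprocessed (and typically [partial_adjust()]ed) cohort
#'   data.frame.
#' @param B bootstrap replicates per scale; values below 100 are refused
#'   unless `allow_small_b` (support estimates would be meaningless).
#' @param scales resample-size ratios for the multiscale bootstrap; must
#'   include 1 (for BP).
#' @param seed integer seed.
#' @param allow_small_b permit B < 100 (for quick exploration only).
#' @return object of class `cluster_support`: list with `hclust`, `nodes`
#'   (the [weighted_hclust()] node table plus columns `bp`, `au`,
#'   `significant`), `bp_by_scale` (nodes x scales matrix), `scales`.
#' @export
cluster_support <- function(table, B = 1000L,
                            scales = seq(0.5, 1.4, by = 0.1),
                            seed = 1L, allow_small_b = FALSE) {
  if (B < 100 && !allow_small_b) {
    stop("B < 100 gives meaningless support estimates; ",
         "set allow_small_b = TRUE to override")
  }
  if (!any(abs(scales - 1) < 1e-9)) scales <- sort(c(scales, 1))
  bms <- biomarker_names(table)
  X <- as.matrix(table[, bms, drop = FALSE])
  w <- table$weight
  n <- nrow(X)

  R <- weighted_corr_matrix(X, w)
  base <- weighted_hclust(R)
  sets <- hclust_member_sets(base$hclust)
  keys <- vapply(sets, paste, character(1), collapse = "+")

  counts <- matrix(0L, length(keys), length(scales),
                   dimnames = list(keys, NULL))
  for (s in seq_along(scales)) {
    m <- ceiling(scales[s] * n)
    set.seed(child_seed(seed, paste0("clusterscale", s)))
    for (b in seq_len(B)) {
      idx <- sample.int(n, m, replace = TRUE)
      Rb <- tryCatch(weighted_corr_matrix(X[idx, , drop = FALSE], w[idx]),
                     error = function(e) NULL)
      if (is.null(Rb)) next
      hb <- stats::hclust(stats::as.dist(1 - Rb), method = "average")
      kb <- vapply(hclust_member_sets(hb), paste, character(1),
                   collapse = "+")
      hit <- keys %in% kb
      counts[hit, s] <- counts[hit, s] + 1L
    }
  }
  bp_by_scale <- counts / B
  s1 <- which(abs(scales - 1) < 1e-9)

  au <- vapply(seq_along(keys), function(k) {
    # a cluster at the boundary on every scale carries no curvature
    # information; its support is decided directly
    if (all(counts[k, ] == B)) return(100)
    if (all(counts[k, ] == 0L)) return(0)
    bp <- pmin(pmax(bp_by_scale[k, ], 1 / (2 * B)), 1 - 1 / (2 * B))
    z <- stats::qnorm(1 - bp)
    # weights from the delta method: var(z) = bp(1-bp) / (B * phi(z)^2)
    wt <- B * stats::dnorm(z)^2 / (bp * (1 - bp))
    D <- cbind(sqrt(scales), 1 / sqrt(scales))
    vc <- tryCatch(
      solve(crossprod(D, wt * D), crossprod(D, wt * z)),
      error = function(e) NULL
    )
    if (is.null(vc)) return(NA_real_)
    100 * (1 - stats::pnorm(vc[1] - vc[2]))
  }, numeric(1))

  nodes <- base$nodes
  nodes$bp <- 100 * bp_by_scale[, s1]
  nodes$au <- pmin(pmax(au, 0), 100)
  nodes$significant <- !is.na(nodes$au) & nodes$au > 95
  structure(
    list(hclust = base$hclust, nodes = nodes,
         bp_by_scale = bp_by_scale, scales = scales, B = B, seed = seed),
    class = "cluster_support"
  )
}

#' Export a supported dendrogram as Newick
#'
#' Writes the clustering as a Newick tree with each internal node
#' labelled `AU|BP` (rounded percentages).
#'
#' @param support a `cluster_support` object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_newick <- function(support, path) {
  tree <- ape::as.phylo(support$hclust)
  parts <- ape::prop.part(tree)
  part_keys <- vapply(parts, function(ix) {
    paste(sort(attr(parts, "labels")[ix]), collapse = "+")
  }, character(1))
  node_key <- support$nodes$members
  lab <- rep("", tree$Nnode)
  for (k in seq_along(part_keys)) {
    hit <- match(part_keys[k], node_key)
    if (!is.na(hit)) {
      lab[k] <- sprintf("%.0f|%.0f", support$nodes$au[hit],
                        support$nodes$bp[hit])
    }
  }
  tree$node.label <- lab
  ape::write.tree(tree, file = path)
  invisible(path)
}
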