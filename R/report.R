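# Reporting conventions: Bonferroni-corrected p-values stored unclamped
# (they may exceed 1, so their negative logs may be negative), display
# capping at 308, and one-decimal summary tables.

#' Negative log10 of a Bonferroni-corrected p-value
#'
#' Returns `-log10(p * family_size)`. The corrected p-value is the raw
#' p-value multiplied by the family size and is deliberately not clamped
#' at 1, so the result can be negative. When the corrected p-value
#' underflows to zero the sentinel cap 308 (the negative log of the
#' smallest representable double) is returned.
#'
#' @param p raw p-value(s) in [0, 1].
#' @param family_size Bonferroni family size (>= 1).
#' @return numeric vector; values above 308 are capped at 308.
#' @export
neg_log_corrected_p <- function(p, family_size = 1L) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  if (family_size < 1) stop("family_size must be >= 1")
  cp <- p * family_size
  out <- ifelse(cp == 0, 308, -log10(cp))
  pmin(out, 308)
}

#' Count significant findings per trajectory class
#'
#' Cross-tabulates trajectory classes with counts and one-decimal
#' percentages of the family size (half-away-from-zero rounding).
#'
#' @param class character vector of class labels (from
#'   [classify_trajectory()]).
#' @param family_size total number of tests in the family.
#' @return data.frame: class, count, percent, label (e.g. "189 (15.4%)").
#' @export
summarize_classes <- function(class, family_size) {
  levels <- c("dec_pp", "dec_pn", "dec_nn", "inc_nn", "inc_np", "inc_pp")
  counts <- vapply(levels, function(l) sum(class == l), integer(1))
  counts <- c(counts,
              decrease = sum(counts[c("dec_pp", "dec_pn", "dec_nn")]),
              increase = sum(counts[c("inc_nn", "inc_np", "inc_pp")]),
              total_significant = sum(class != "none"))
  pct <- round_half_up(100 * counts / family_size, 1L)
  data.frame(
    class = names(counts),
    count = as.integer(counts),
    percent = pct,
    label = sprintf("%d (%.1f%%)", counts, pct),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Summary table of trajectory findings by sign behaviour
#'
#' Arranges significant trajectory counts as sign-switching vs
#' sign-preserving (remains positive / remains negative) against
#' increasing vs decreasing trends, with one-decimal percentages of the
#' family size.
#'
#' @param class character vector of class labels.
#' @param family_size total number of tests in the family.
#' @return data.frame with rows switches/remains_positive/
#'   remains_negative/total and columns for increase, decrease, total.
#' @export
trajectory_summary_table <- function(class, family_size) {
  cell <- function(n) sprintf("%d (%.1f%%)", n,
                              round_half_up(100 * n / family_size, 1L))
  inc <- c(switches = sum(class == "inc_np"),
           remains_positive = sum(class == "inc_pp"),
           remains_negative = sum(class == "inc_nn"))
  dec <- c(switches = sum(class == "dec_pn"),
           remains_positive = sum(class == "dec_pp"),
           remains_negative = sum(class == "dec_nn"))
  rows <- c("switches", "remains_positive", "remains_negative")
  out <- data.frame(
    trajectory = c(rows, "total"),
    increases = cell(c(inc[rows], sum(inc))),
    decreases = cell(c(dec[rows], sum(dec))),
    total = cell(c(inc[rows] + dec[rows], sum(inc) + sum(dec))),
    stringsAsFactors = FALSE
  )
  out
}

#' Volcano-plot data for a set of trajectory fits or comparisons
#'
#' @param fits data.frame with columns `slope` (or `diff`),
#'   `neg_log_corrected_p` and `class` (optional).
#' @param x name of the column to use as the x axis.
#' @return data.frame with columns `x`, `y`, `class`, ready to plot.
#' @export
volcano_data <- function(fits, x = "slope") {
  data.frame(
    x = fits[[x]],
    y = fits$neg_log_corrected_p,
    class = if ("class" %in% names(fits)) fits$class else "none",
    stringsAsFactors = FALSE
  )
}

#' Write a machine-readable run manifest
#'
#' Records the seed, package version and any configuration values so a
#' run can be reproduced exactly.
#'
#' @param path output JSON path.
#' @param seed integer seed used for the run.
#' @param ... further named configuration entries to record.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(path, seed, ...) {
  manifest <- list(
    seed = seed,
    package = "agecodep",
    version = as.character(utils::packageVersion("agecodep")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = list(...)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
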