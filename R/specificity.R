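# Enhancer specificity: aggregated accessibility over enhancer intervals,
# gini index, Spearman accessibility-vs-activity, and specificity classes.

#' Aggregate region-cell probabilities over enhancer intervals
#'
#' Enhancer-reporter constructs are typically broad (1-5 kb) and contain one
#' or more accessible regions; the accessibility of such an interval is the
#' sum of the region-cell probabilities of the member regions (any overlap of
#' at least 1 bp). Intervals with no member region get zero rows and are
#' listed in the `"empty"` attribute.
#'
#' @param rc Region x cell accessibility matrix.
#' @param intervals Region table of enhancer intervals.
#' @param regions Region table matching the rows of `rc`.
#' @return Interval x cell matrix; member region ids per interval are attached
#'   as attribute `members`.
#' @export
aggregate_interval_accessibility <- function(rc, intervals, regions) {
  check_regions(intervals, "intervals")
  check_regions(regions)
  out <- matrix(0, nrow(intervals), ncol(rc),
                dimnames = list(intervals$id, colnames(rc)))
  hits <- GenomicRanges::findOverlaps(regions_to_granges(intervals),
                                      regions_to_granges(regions))
  members <- split(regions$id[S4Vectors::subjectHits(hits)],
                   intervals$id[S4Vectors::queryHits(hits)])
  for (iv in names(members))
    out[iv, ] <- colSums(rc[members[[iv]], , drop = FALSE])
  attr(out, "members") <- members
  attr(out, "empty") <- setdiff(intervals$id, names(members))
  out
}

#' Gini index of an accessibility vector
#'
#' Population form: `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, computed via
#' the equivalent O(n log n) sorted expression. G is 0 for a uniform vector
#' (equally accessible in all cells), reaches its maximum `(n-1)/n` for a
#' one-hot vector (accessible in a single cell), and is invariant to positive
#' rescaling.
#'
#' @param x Non-negative numeric vector, length >= 2, positive sum.
#' @return The gini index in `[0, (n-1)/n]`.
#' @export
gini_index <- function(x) {
  if (length(x) < 2L) stopf("need at least 2 values")
  if (any(x < 0)) stopf("values must be non-negative")
  s <- sum(x)
  if (s <= 0) stopf("all-zero vector: gini undefined")
  n <- length(x)
  xs <- sort(x)
  (2 * sum(seq_len(n) * xs) / (n * s)) - (n + 1) / n
}

#' Spearman correlation between accessibility and binary activity
#'
#' Rank correlation with midrank tie handling (binary activity vectors are
#' almost entirely ties, so midranks are essential). Returns NA with a
#' `"constant"` flag when either vector is constant.
#'
#' @param acc Numeric accessibility over virtual cells.
#' @param act Binary (0/1) activity over the same virtual cells.
#' @return Spearman's rho, or flagged NA.
#' @export
accessibility_activity_correlation <- function(acc, act) {
  if (length(acc) != length(act)) stopf("length mismatch")
  if (!all(act %in% c(0, 1))) stopf("activity must be binary 0/1")
  if (stats::var(acc) == 0 || stats::var(act) == 0) {
    out <- NA_real_
    attr(out, "constant") <- TRUE
    return(out)
  }
  stats::cor(acc, act, method = "spearman")
}

#' Classify enhancers by accessibility specificity
#'
#' Generally accessible enhancers have gini below `g_low` (default 0.2),
#' specific enhancers above `g_high` (default 0.4); the rest are intermediate.
#'
#' @param gini Numeric vector of gini indices.
#' @param g_low,g_high Class thresholds.
#' @return Character vector in `{general, intermediate, specific}`.
#' @export
classify_enhancers <- function(gini, g_low = 0.2, g_high = 0.4) {
  ifelse(gini < g_low, "general", ifelse(gini > g_high, "specific", "intermediate"))
}

#' Per-enhancer specificity report
#'
#' Convenience wrapper running aggregation, gini, Spearman-vs-activity and
#' classification for a set of enhancer intervals.
#'
#' @param rc Region x virtual-cell accessibility matrix.
#' @param intervals Enhancer interval table.
#' @param regions Region table.
#' @param activity Enhancer x virtual-cell binary activity matrix (rows
#'   matching interval ids; optional).
#' @param g_low,g_high Gini class thresholds.
#' @return data.frame (`enhancer_id`, `gini`, `spearman_rho`, `class`,
#'   `n_member_regions`).
#' @export
enhancer_report <- function(rc, intervals, regions, activity = NULL,
                            g_low = 0.2, g_high = 0.4) {
  agg <- aggregate_interval_accessibility(rc, intervals, regions)
  members <- attr(agg, "members")
  gini <- vapply(rownames(agg), function(iv) {
    if (sum(agg[iv, ]) <= 0) NA_real_ else gini_index(agg[iv, ])
  }, numeric(1))
  rho <- rep(NA_real_, nrow(agg))
  if (!is.null(activity)) {
    for (i in seq_len(nrow(agg))) {
      iv <- rownames(agg)[i]
      if (iv %in% rownames(activity) && sum(agg[iv, ]) > 0)
        rho[i] <- accessibility_activity_correlation(agg[iv, ],
                                                     activity[iv, colnames(agg)])
    }
  }
  n_members <- lengths(members)[rownames(agg)]
  n_members[is.na(n_members)] <- 0L
  data.frame(
    enhancer_id = rownames(agg), gini = unname(gini), spearman_rho = rho,
    class = ifelse(is.na(gini), NA_character_, classify_enhancers(gini, g_low, g_high)),
    n_member_regions = unname(n_members)
  )
}
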