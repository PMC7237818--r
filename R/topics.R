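# Topic-model handling: region-cell predictive distribution and topic
# binarization.
#
# A topic model of chromatin accessibility decomposes a region-by-cell count
# matrix into a region-topic distribution (each topic is a probability
# distribution over regions; topics are sets of co-accessible regions) and a
# topic-cell distribution (each cell is a probability distribution over
# topics).

#' Construct a topic model object
#'
#' @param region_topic R x T matrix; every column is a probability
#'   distribution over regions (sums to 1, tolerance 1e-6).
#' @param topic_cell T x C matrix; every column is a probability distribution
#'   over topics.
#' @param tol Column-sum tolerance.
#' @return A list of class `topic_model`.
#' @export
topic_model <- function(region_topic, topic_cell, tol = 1e-6) {
  check_named_matrix(region_topic, "region_topic")
  check_named_matrix(topic_cell, "topic_cell")
  if (!setequal(colnames(region_topic), rownames(topic_cell)))
    stopf("topic ids of region_topic and topic_cell do not match")
  topic_cell <- topic_cell[colnames(region_topic), , drop = FALSE]
  if (any(region_topic < 0) || any(topic_cell < 0))
    stopf("topic model entries must be non-negative")
  if (any(abs(colSums(region_topic) - 1) > tol))
    stopf("region_topic columns must sum to 1")
  if (any(abs(colSums(topic_cell) - 1) > tol))
    stopf("topic_cell columns must sum to 1")
  structure(list(region_topic = region_topic, topic_cell = topic_cell),
            class = "topic_model")
}

#' Region-cell predictive distribution
#'
#' Multiplies the region-topic and topic-cell distributions to obtain the
#' probability of each region in each cell. Because both factors are
#' column-stochastic, every column of the product sums to 1; the product also
#' acts as a dropout-imputation step, spreading topic-level accessibility back
#' over regions.
#'
#' @param model A `topic_model`.
#' @return R x C matrix of region-cell accessibility probabilities.
#' @export
predictive_distribution <- function(model) {
  stopifnot(inherits(model, "topic_model"))
  model$region_topic %*% model$topic_cell
}

#' Binarize topics into region sets
#'
#' For each topic, regions are ranked by their topic probability and the top
#' regions forming the upper `1 - threshold` tail of the topic's probability
#' mass are selected: a region is kept while the cumulative probability of the
#' regions ranked above it is still below `1 - threshold`. At the default
#' threshold of 0.985 each topic therefore keeps the regions carrying its top
#' 1.5% of probability mass. The selected set shrinks monotonically as the
#' threshold grows and is empty at threshold 1.
#'
#' @param model A `topic_model`.
#' @param threshold Probability threshold in (0, 1]; default 0.985.
#' @return Named list mapping topic id to a character vector of region ids.
#' @export
binarize_topics <- function(model, threshold = 0.985) {
  stopifnot(inherits(model, "topic_model"))
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  rt <- model$region_topic
  out <- lapply(colnames(rt), function(t) {
    p <- rt[, t]
    ord <- order(p, names(p), decreasing = c(TRUE, FALSE), method = "radix")
    p <- p[ord]
    cum_before <- cumsum(c(0, p[-length(p)]))
    names(p)[cum_before < (1 - threshold) & p > 0]
  })
  stats::setNames(out, colnames(rt))
}
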