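# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a stage-specific seed from a global seed
#'
#' Stage seeds are derived by hashing the stage name into a 32-bit integer and
#' mixing it with the global seed, so that every stochastic stage of a run gets
#' its own reproducible stream without seed collisions between stages.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"rf:geneA"`).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 31 + v) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 7919 + h) %% 2147483629)
}

# Equal-count (quantile) binning with stable id tie-breaking.
# Returns a named integer vector of bin indices (1 = first after orienting).
# Sizes differ by at most 1; if fewer items than bins, each item gets its own
# bin and a warning is raised (degenerate bins).
equal_count_bins <- function(ids, values, n_bins, decreasing = FALSE) {
  stopifnot(length(ids) == length(values), n_bins >= 1)
  n <- length(ids)
  if (n == 0L) return(stats::setNames(integer(0), character(0)))
  ord <- order(values, ids, decreasing = c(decreasing, FALSE), method = "radix")
  if (n < n_bins) {
    warnf("fewer items (%d) than bins (%d): bins collapse to one item each", n, n_bins)
    bins <- seq_len(n)
  } else {
    sizes <- diff(floor(seq(0, n, length.out = n_bins + 1)))
    bins <- rep.int(seq_len(n_bins), times = sizes)
  }
  out <- integer(n)
  out[ord] <- bins
  stats::setNames(out, ids)
}

# Validate a dense named matrix: unique, non-empty dimnames.
check_named_matrix <- function(x, what = "matrix") {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("%s must have row and column names", what)
  if (anyDuplicated(rownames(x))) stopf("duplicate row ids in %s", what)
  if (anyDuplicated(colnames(x))) stopf("duplicate column ids in %s", what)
  invisible(x)
}

# Region data.frame (chrom, start, end, id; 0-based half-open) -> GRanges
# (1-based closed, as GenomicRanges expects).
regions_to_granges <- function(regions) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
  names(gr) <- regions$id
  gr
}

check_regions <- function(regions, what = "regions") {
  need <- c("chrom", "start", "end", "id")
  if (!all(need %in% names(regions)))
    stopf("%s must have columns %s", what, paste(need, collapse = ", "))
  if (any(regions$start >= regions$end))
    stopf("%s: start >= end for id(s) %s", what,
          paste(utils::head(regions$id[regions$start >= regions$end], 3), collapse = ", "))
  if (anyDuplicated(regions$id)) stopf("%s: duplicate region ids", what)
  invisible(regions)
}
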