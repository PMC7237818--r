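# Step-function binarization of a real-valued vector (BASC-A style).
#
# The procedure: sort the values ascending; for every number of
# discontinuities d = 1 .. n-2, compute the step function with d jumps that
# minimizes the total squared error (dynamic programming over block
# partitions); in each optimal step function locate the strongest
# discontinuity (the jump with the largest height between adjacent block
# means, ties to the lower position); take the median of these strongest
# locations across all step functions and place the threshold at the midpoint
# of that jump. Values strictly above the threshold form the selected set,
# which is never empty and is invariant to the input order.

#' Binarize non-negative values at their strongest discontinuity
#'
#' @param values Named (or unnamed) numeric vector, length >= 3, not all
#'   equal.
#' @return A list with `threshold` (numeric) and `selected` (names, or
#'   indices when unnamed, of the values strictly above the threshold).
#' @export
basc_binarize <- function(values) {
  if (length(values) < 3L) stopf("need at least 3 values")
  if (any(values < 0)) stopf("values must be non-negative")
  if (max(values) - min(values) <= 0) stopf("degenerate input: all values equal")
  ids <- names(values) %||% as.character(seq_along(values))
  y <- sort(as.numeric(values))
  n <- length(y)

  # prefix sums for O(1) block SSE
  cs <- cumsum(y)
  cs2 <- cumsum(y^2)
  block_sse <- function(i, j) { # SSE of y[i..j] around its mean
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  block_mean <- function(i, j) (cs[j] - if (i > 1) cs[i - 1] else 0) / (j - i + 1)

  # dp[k, j]: minimal SSE of partitioning y[1..j] into k blocks
  max_d <- n - 2L # discontinuities
  dp <- matrix(Inf, max_d + 1L, n)
  bt <- matrix(0L, max_d + 1L, n)
  for (j in seq_len(n)) dp[1L, j] <- block_sse(1L, j)
  if (max_d >= 1L) {
    for (k in seq(2L, max_d + 1L)) {
      for (j in seq(k, n)) {
        best <- Inf; arg <- 0L
        for (m in seq(k - 1L, j - 1L)) {
          v <- dp[k - 1L, m] + block_sse(m + 1L, j)
          if (v < best - 1e-15) { best <- v; arg <- m }
        }
        dp[k, j] <- best
        bt[k, j] <- arg
      }
    }
  }

  strongest <- integer(max_d)
  for (d in seq_len(max_d)) {
    # recover breakpoints of the optimal (d+1)-block partition
    brk <- integer(d)
    j <- n
    for (k in seq(d + 1L, 2L)) {
      brk[k - 1L] <- bt[k, j]
      j <- bt[k, j]
    }
    # adjacent block means around each breakpoint
    bounds <- c(0L, brk, n)
    heights <- vapply(seq_len(d), function(b) {
      block_mean(bounds[b + 1L] + 1L, bounds[b + 2L]) -
        block_mean(bounds[b] + 1L, bounds[b + 1L])
    }, numeric(1))
    strongest[d] <- brk[which.max(heights)]
  }
  loc <- sort(strongest)[ceiling(length(strongest) / 2)] # lower median
  threshold <- (y[loc] + y[loc + 1L]) / 2
  list(threshold = threshold, selected = ids[values > threshold])
}
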