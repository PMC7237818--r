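# Position-weight-matrix text IO (Cluster-Buster-style blocks).

#' Construct a PWM object
#'
#' @param motif_id Motif identifier.
#' @param probs L x 4 matrix of base probabilities, columns A, C, G, T; each
#'   row must sum to 1 (tolerance 1e-6) and L must be at least 4.
#' @param background Length-4 background distribution (default uniform).
#' @return A list of class `pwm`.
#' @export
pwm <- function(motif_id, probs, background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stopf("PWM %s: probs must have 4 columns (A,C,G,T)", motif_id)
  if (nrow(probs) < 4L) stopf("PWM %s: motif length must be >= 4", motif_id)
  if (any(abs(rowSums(probs) - 1) > 1e-6)) stopf("PWM %s: rows must sum to 1", motif_id)
  if (abs(sum(background) - 1) > 1e-6) stopf("PWM %s: background must sum to 1", motif_id)
  colnames(probs) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, probs = probs, background = background),
            class = "pwm")
}

#' Read PWMs from a Cluster-Buster-style text file
#'
#' Each motif is a block starting with `>motif_id` followed by one row of four
#' non-negative counts (or probabilities) per position, columns A, C, G, T.
#' Count rows are converted to probabilities with a pseudocount per cell and
#' renormalized; a row of all zeros (before pseudocount) is an error, as is an
#' empty block.
#'
#' @param path Path to the motif file.
#' @param pseudocount Pseudocount added to each cell (default 1).
#' @param background Background distribution attached to every motif.
#' @return A named list of `pwm` objects.
#' @export
read_pwms <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  if (!file.exists(path)) stopf("PWM file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0L) stopf("no motif blocks found in %s", path)
  bounds <- c(heads, length(lines) + 1L)
  out <- list()
  for (i in seq_along(heads)) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    body <- lines[seq(heads[i] + 1L, bounds[i + 1L] - 1L)]
    if (heads[i] + 1L > bounds[i + 1L] - 1L || length(body) == 0L)
      stopf("empty motif block '%s' in %s", id, path)
    counts <- t(vapply(strsplit(body, "[ \t]+"), function(p) as.numeric(p[1:4]), numeric(4)))
    if (anyNA(counts) || any(counts < 0))
      stopf("motif '%s': malformed or negative count row", id)
    if (any(rowSums(counts) == 0)) stopf("motif '%s': row of all zeros", id)
    probs <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
    out[[id]] <- pwm(id, probs, background)
  }
  out
}

#' Write PWMs to a Cluster-Buster-style text file
#'
#' Probabilities are written scaled to counts out of 100 per row (exact
#' probabilities are recovered on read only up to the pseudocount convention;
#' this writer exists for interoperability, not lossless round trips).
#'
#' @param pwms Named list of `pwm` objects.
#' @param path Output path.
#' @param scale Total count per row (default 100).
#' @export
write_pwms <- function(pwms, path, scale = 100) {
  lines <- character(0)
  for (p in pwms) {
    lines <- c(lines, paste0(">", p$motif_id),
               apply(round(p$probs * scale, 6), 1,
                     function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = "\t")))
  }
  writeLines(lines, path)
  invisible(path)
}
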