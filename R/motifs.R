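# PWM scanning: best log2 odds hit over all windows and both strands.

# Encode a DNA string as integers 1..4 (A,C,G,T); anything else (N, gaps)
# becomes NA and poisons any window containing it.
encode_seq <- function(seq) {
  match(strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]],
        c("A", "C", "G", "T"))
}

revcomp_code <- function(code) 5L - rev(code)

# Best window score of an encoded sequence against an L x 4 log-odds matrix.
scan_best <- function(code, lo) {
  len <- nrow(lo)
  w <- length(code) - len + 1L
  if (w < 1L) return(-Inf)
  s <- numeric(w)
  for (j in seq_len(len)) {
    v <- lo[j, code[j:(j + w - 1L)]]
    v[is.na(v)] <- -Inf
    s <- s + v
  }
  max(s)
}

#' Best motif match score in a sequence
#'
#' The score of a window is `sum_positions log2(p_base / background_base)`;
#' the returned value is the maximum over all windows on both strands (the
#' best single-motif hit, which for one motif dominates cluster-style CRM
#' scores). Windows containing non-ACGT characters score `-Inf`; a sequence
#' shorter than the motif returns `-Inf` with a `"too_short"` flag.
#'
#' @param seq Character DNA sequence (or `DNAString`).
#' @param pwm A [pwm()] object.
#' @return Best log2-odds score (possibly `-Inf`).
#' @export
motif_best_score <- function(seq, pwm) {
  stopifnot(inherits(pwm, "pwm"))
  code <- encode_seq(seq)
  if (length(code) < nrow(pwm$probs)) {
    out <- -Inf
    attr(out, "too_short") <- TRUE
    return(out)
  }
  lo <- log2(pwm$probs / rep(pwm$background, each = nrow(pwm$probs)))
  max(scan_best(code, lo), scan_best(revcomp_code(code), lo))
}

# Batch scanner used by delta_scores: motifs x sequences matrix of best
# scores, reusing encodings and log-odds matrices.
best_scores_matrix <- function(seqs, pwms) {
  codes <- lapply(seqs, encode_seq)
  rcs <- lapply(codes, revcomp_code)
  los <- lapply(pwms, function(p) log2(p$probs / rep(p$background, each = nrow(p$probs))))
  out <- matrix(-Inf, length(pwms), length(seqs),
                dimnames = list(names(pwms), names(seqs)))
  for (m in seq_along(pwms)) {
    lo <- los[[m]]
    for (s in seq_along(codes))
      out[m, s] <- max(scan_best(codes[[s]], lo), scan_best(rcs[[s]], lo))
  }
  out
}
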