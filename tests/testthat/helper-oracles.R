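# Independent oracles and small shared fixtures.

# O(n^2) pairwise gini oracle.
gini_pairwise <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, `-`))) / (2 * n^2 * mean(x))
}

# Brute-force best PWM hit: explicit loops over windows and strands.
brute_best_score <- function(seq, pwm) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_one <- function(chars) {
    len <- nrow(pwm$probs)
    if (length(chars) < len) return(-Inf)
    best <- -Inf
    for (s in seq_len(length(chars) - len + 1)) {
      sc <- 0
      for (j in seq_len(len)) {
        b <- match(chars[s + j - 1], bases)
        if (is.na(b)) { sc <- -Inf; break }
        sc <- sc + log2(pwm$probs[j, b] / pwm$background[b])
      }
      best <- max(best, sc)
    }
    best
  }
  fwd <- strsplit(toupper(seq), "")[[1]]
  rev <- rev(unname(comp[fwd]))
  rev[is.na(rev)] <- "N"
  max(score_one(fwd), score_one(rev))
}

# Exhaustive two-block split: the single split point minimizing total SSE.
best_two_block_split <- function(y) {
  y <- sort(y)
  n <- length(y)
  sse <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
  costs <- vapply(seq_len(n - 1), function(s) sse(y[1:s]) + sse(y[(s + 1):n]),
                  numeric(1))
  which.min(costs)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# A tiny two-type template: 6 "stripe" pixels with an axis landmark and a
# 4-pixel "ring" with a radial landmark.
tiny_template <- function() {
  cells <- data.frame(
    vcell_id = sprintf("v%02d", 1:10),
    x = c(1, 2, 3, 4, 5, 6, 10, 10, 12, 12),
    y = c(1, 1, 1, 1, 1, 1, 5, 7, 5, 7),
    cell_type = c(rep("stripe", 6), rep("ring", 4)),
    spatial = TRUE
  )
  virtual_template(cells, list(
    landmark("stripe", "axis_x", x0 = 0, direction = "increasing"),
    landmark("ring", "radial", x0 = 11, y0 = 6, direction = "increasing")
  ))
}

# Evaluate a generated tissue's gene profile at latent positions u.
profile_at <- function(bundle, gene_id, u, cell_type) {
  gp <- bundle$truth$gene_profiles
  row <- gp[gp$gene_id == gene_id, ]
  f <- switch(row$kind,
              rise = function(u) 1 / (1 + exp(-row$steep * (u - row$center))),
              fall = function(u) 1 - 1 / (1 + exp(-row$steep * (u - row$center))),
              bump = function(u) exp(-(u - row$center)^2 / (2 * 0.15^2)))
  ifelse(cell_type == row$home_type, 0.1 + 0.9 * f(u), 0.05)
}
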