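# Chromatin-accessibility QTLs across an inbred panel and their motif-level
# consequences.
#
# Each SNP inside an accessible region is tested for association between its
# binary genotype across lines and the region's normalized accessibility
# (Gaussian GLM, i.e. ordinary least squares with a Wald t-test on the
# genotype slope), with Benjamini-Hochberg adjustment across all tested
# pairs. Significant SNPs (caQTLs) are classified as chromatin-opening
# (slope > 0 per alternate allele) or closing. For motif-level consequences,
# each caQTL region yields two allele sequences (the more-accessible "open"
# allele and the "closed" allele); the difference in a motif's best match
# score between them is its delta score, and motifs whose |delta| exceeds a
# cutoff significantly more often among caQTLs than among control SNPs
# (no-effect SNPs in accessible regions) are reported by a one-sided Fisher
# test.

#' CPM-normalize a region-by-line count matrix
#'
#' Counts-per-million per line (column scaling); optionally log1p-transformed.
#'
#' @param counts Region x line non-negative integer matrix.
#' @param log1p Apply `log1p` after scaling (default FALSE).
#' @return Region x line numeric matrix.
#' @export
normalize_counts <- function(counts, log1p = FALSE) {
  depth <- colSums(counts)
  if (any(depth <= 0))
    stopf("zero-depth line(s): %s",
          paste(colnames(counts)[depth <= 0], collapse = ", "))
  out <- sweep(counts, 2, depth / 1e6, `/`)
  if (log1p) out <- log1p(out)
  out
}

#' Assign SNPs to their encompassing regions
#'
#' A SNP is assigned to every region containing its position (half-open
#' containment: `start <= pos < end`); SNPs outside all regions are dropped.
#' SNPs in overlapping regions yield one pair per region.
#'
#' @param genotypes A `genotype_matrix`.
#' @param regions Region table.
#' @return data.frame (`snp_id`, `region_id`).
#' @export
assign_snps_to_regions <- function(genotypes, regions) {
  check_regions(regions)
  snps <- genotypes$snps
  gr_snp <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos + 1L, snps$pos + 1L))
  hits <- GenomicRanges::findOverlaps(gr_snp, regions_to_granges(regions))
  data.frame(snp_id = snps$snp_id[S4Vectors::queryHits(hits)],
             region_id = regions$id[S4Vectors::subjectHits(hits)])
}

#' Scan SNP-region pairs for accessibility QTLs
#'
#' Per pair, an ordinary least-squares fit of normalized accessibility on the
#' binary genotype over the lines with a non-NA genotype (equivalent to the
#' default Gaussian GLM), two-sided Wald t-test on the slope, then BH
#' adjustment across all tested pairs. Pairs with fewer than `min_lines`
#' informative lines or fewer than `min_per_class` lines in either genotype
#' class (including monomorphic SNPs) are skipped and counted in the
#' `"skipped"` attribute.
#'
#' @param norm_acc Region x line normalized accessibility matrix.
#' @param genotypes A `genotype_matrix` (columns matching `norm_acc`).
#' @param assignment SNP-region pairs from [assign_snps_to_regions()].
#' @param min_lines Minimum informative lines per pair (default 10).
#' @param min_per_class Minimum lines per genotype class (default 3).
#' @param fdr_max caQTL call threshold on the adjusted p-value (default 0.05;
#'   stored in the `caqtl` column).
#' @return data.frame of class `caqtl_result` (`snp_id`, `region_id`, `beta`,
#'   `p`, `fdr`, `direction`, `n_lines`, `caqtl`).
#' @export
caqtl_scan <- function(norm_acc, genotypes, assignment, min_lines = 10,
                       min_per_class = 3, fdr_max = 0.05) {
  lines <- colnames(norm_acc)
  if (!all(lines %in% colnames(genotypes$values)))
    stopf("genotype matrix missing line(s) present in accessibility matrix")
  gvals <- genotypes$values[, lines, drop = FALSE]
  n_pairs <- nrow(assignment)
  beta <- p <- rep(NA_real_, n_pairs)
  n_used <- integer(n_pairs)
  skipped <- 0L
  for (i in seq_len(n_pairs)) {
    g <- gvals[assignment$snp_id[i], ]
    y <- norm_acc[assignment$region_id[i], ]
    ok <- !is.na(g)
    g <- g[ok]; y <- y[ok]
    n <- length(g)
    n1 <- sum(g == 1)
    if (n < min_lines || n1 < min_per_class || (n - n1) < min_per_class) {
      skipped <- skipped + 1L
      next
    }
    gm <- g - mean(g)
    sxx <- sum(gm^2)
    b <- sum(gm * y) / sxx
    resid <- y - mean(y) - b * gm
    s2 <- sum(resid^2) / (n - 2)
    tval <- b / sqrt(s2 / sxx)
    beta[i] <- b
    p[i] <- 2 * stats::pt(-abs(tval), df = n - 2)
    n_used[i] <- n
  }
  tested <- !is.na(p)
  fdr <- rep(NA_real_, n_pairs)
  fdr[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(
    snp_id = assignment$snp_id, region_id = assignment$region_id,
    beta = beta, p = p, fdr = fdr,
    direction = ifelse(is.na(beta), NA_character_,
                       ifelse(beta > 0, "opening", "closing")),
    n_lines = n_used, caqtl = !is.na(fdr) & fdr < fdr_max
  )
  attr(out, "skipped") <- skipped
  class(out) <- c("caqtl_result", "data.frame")
  out
}

#' Sample control SNPs with no accessibility effect
#'
#' A uniform seeded sample (of size `min(n, pool)`) among tested SNPs whose
#' adjusted p-value exceeds `fdr_min` — SNPs sitting in accessible regions
#' but showing no association with accessibility.
#'
#' @param results A `caqtl_result`.
#' @param fdr_min Eligibility threshold (default 0.95).
#' @param n Sample size cap (default 20000).
#' @param seed Integer seed.
#' @return Character vector of snp ids (empty, with a warning, if none are
#'   eligible).
#' @export
select_control_snps <- function(results, fdr_min = 0.95, n = 20000, seed = 1L) {
  pool <- unique(results$snp_id[!is.na(results$fdr) & results$fdr > fdr_min])
  if (length(pool) == 0L) {
    warnf("no SNPs with FDR > %g: empty control set", fdr_min)
    return(character(0))
  }
  pool <- sort(pool)
  if (length(pool) <= n) return(pool)
  withr::with_seed(seed, sort(sample(pool, n)))
}

#' Allele sequences of a caQTL region
#'
#' Extracts the region sequence from the genome and returns two copies
#' differing only at the SNP position: the allele associated with higher
#' accessibility (by the sign of the slope) in `seq_open`, the other in
#' `seq_closed`. The reference allele must match the genome at the SNP
#' position.
#'
#' @param snp One row of a `genotype_matrix`'s `snps` table.
#' @param region One row of a region table.
#' @param fasta A named `DNAStringSet` (e.g. from
#'   `Biostrings::readDNAStringSet`) or a named character vector of
#'   chromosome sequences.
#' @param beta Slope of the caQTL fit (accessibility per alternate allele).
#' @return list(`seq_open`, `seq_closed`) as character strings.
#' @export
allele_sequences <- function(snp, region, fasta, beta) {
  chrom_seq <- as.character(fasta[[region$chrom]])
  if (is.null(chrom_seq) || is.na(chrom_seq))
    stopf("chromosome '%s' absent from FASTA", region$chrom)
  seq <- substr(chrom_seq, region$start + 1L, region$end)
  off <- snp$pos - region$start + 1L
  if (off < 1L || off > nchar(seq))
    stopf("SNP %s outside region %s", snp$snp_id, region$id)
  at <- substr(seq, off, off)
  if (toupper(at) != toupper(snp$ref))
    stopf("reference mismatch at %s:%d: FASTA has '%s', VCF ref is '%s'",
          snp$chrom, snp$pos, at, snp$ref)
  with_allele <- function(a) {
    s <- seq
    substr(s, off, off) <- a
    s
  }
  if (beta > 0) {
    list(seq_open = with_allele(snp$alt), seq_closed = with_allele(snp$ref))
  } else {
    list(seq_open = with_allele(snp$ref), seq_closed = with_allele(snp$alt))
  }
}

#' Delta motif scores between open and closed allele sequences
#'
#' `delta(motif) = best_score(seq_open) - best_score(seq_closed)`. When a
#' motif has no finite hit in either sequence the delta is 0 (best hit
#' unchanged). Swapping the open/closed labels negates every delta.
#'
#' @param seq_open,seq_closed Equal-length allele sequences.
#' @param pwms Named list of [pwm()] objects.
#' @return data.frame (`motif_id`, `delta`).
#' @export
delta_scores <- function(seq_open, seq_closed, pwms) {
  if (nchar(seq_open) != nchar(seq_closed)) stopf("allele sequences differ in length")
  sc <- best_scores_matrix(list(open = seq_open, closed = seq_closed), pwms)
  delta <- sc[, "open"] - sc[, "closed"]
  delta[!is.finite(sc[, "open"]) & !is.finite(sc[, "closed"])] <- 0
  data.frame(motif_id = rownames(sc), delta = unname(delta))
}

# Motif x SNP delta matrix for a set of (snp, region, beta) rows.
delta_matrix <- function(snp_table, genotypes, regions, fasta, pwms) {
  out <- matrix(NA_real_, length(pwms), nrow(snp_table),
                dimnames = list(names(pwms), snp_table$snp_id))
  snp_rows <- genotypes$snps
  for (i in seq_len(nrow(snp_table))) {
    snp <- snp_rows[snp_rows$snp_id == snp_table$snp_id[i], , drop = FALSE]
    region <- regions[regions$id == snp_table$region_id[i], , drop = FALSE]
    seqs <- allele_sequences(snp, region, fasta, snp_table$beta[i])
    out[, i] <- delta_scores(seqs$seq_open, seqs$seq_closed, pwms)$delta
  }
  out
}

#' Motif enrichment among caQTLs versus control SNPs
#'
#' Per motif, a 2x2 table of (caQTL vs control SNP) by (|delta| > cutoff vs
#' not) is tested with a one-sided Fisher exact test (alternative: caQTLs
#' more affected), followed by BH adjustment across motifs. A table with a
#' zero margin gives p = 1. The cumulative delta is the sum of the motif's
#' deltas over the caQTL set.
#'
#' @param deltas_caqtl Motif x caQTL delta matrix.
#' @param deltas_control Motif x control delta matrix (same motifs).
#' @param abs_delta_min |delta| cutoff defining "affected" (default 3).
#' @return data.frame (`motif_id`, `n_caqtl_affected`, `n_caqtl`,
#'   `n_control_affected`, `n_control`, `odds_ratio`, `p`, `adj_p`,
#'   `cumulative_delta`), sorted by adjusted p.
#' @export
motif_enrichment <- function(deltas_caqtl, deltas_control, abs_delta_min = 3) {
  if (ncol(deltas_caqtl) == 0L || ncol(deltas_control) == 0L)
    stopf("both caQTL and control delta sets must be non-empty")
  stopifnot(identical(rownames(deltas_caqtl), rownames(deltas_control)))
  motifs <- rownames(deltas_caqtl)
  res <- lapply(motifs, function(m) {
    a <- sum(abs(deltas_caqtl[m, ]) > abs_delta_min)
    b <- ncol(deltas_caqtl) - a
    cc <- sum(abs(deltas_control[m, ]) > abs_delta_min)
    d <- ncol(deltas_control) - cc
    tab <- matrix(c(a, cc, b, d), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      p <- 1; or <- NA_real_
    } else {
      ft <- stats::fisher.test(tab, alternative = "greater")
      p <- ft$p.value
      or <- unname(ft$estimate)
    }
    data.frame(motif_id = m, n_caqtl_affected = a, n_caqtl = a + b,
               n_control_affected = cc, n_control = cc + d,
               odds_ratio = or, p = p,
               cumulative_delta = sum(deltas_caqtl[m, ]))
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$adj_p, out$p, out$motif_id), ]
  rownames(out) <- NULL
  out[, c("motif_id", "n_caqtl_affected", "n_caqtl", "n_control_affected",
          "n_control", "odds_ratio", "p", "adj_p", "cumulative_delta")]
}

#' Per-topic motif enrichment
#'
#' Restricts caQTLs and controls to SNPs whose region belongs to each topic's
#' binarized region set and runs [motif_enrichment()] per topic. Topics with
#' no caQTL or no control SNP are reported with NA statistics.
#'
#' @param deltas_caqtl,deltas_control Motif x SNP delta matrices.
#' @param caqtl_regions Named vector snp id -> region id for the caQTL SNPs.
#' @param control_regions Same for control SNPs.
#' @param binarized_topics Named list topic -> region ids (see
#'   [binarize_topics()]).
#' @param abs_delta_min |delta| cutoff (default 3).
#' @return data.frame with a `topic` column prepended to the
#'   [motif_enrichment()] columns.
#' @export
per_topic_enrichment <- function(deltas_caqtl, deltas_control, caqtl_regions,
                                 control_regions, binarized_topics,
                                 abs_delta_min = 3) {
  out <- list()
  for (topic in names(binarized_topics)) {
    regs <- binarized_topics[[topic]]
    qc <- names(caqtl_regions)[caqtl_regions %in% regs]
    cc <- names(control_regions)[control_regions %in% regs]
    if (length(qc) == 0L || length(cc) == 0L) {
      out[[topic]] <- data.frame(
        topic = topic, motif_id = rownames(deltas_caqtl),
        n_caqtl_affected = NA_integer_, n_caqtl = length(qc),
        n_control_affected = NA_integer_, n_control = length(cc),
        odds_ratio = NA_real_, p = NA_real_, adj_p = NA_real_,
        cumulative_delta = NA_real_)
      next
    }
    enr <- motif_enrichment(deltas_caqtl[, qc, drop = FALSE],
                            deltas_control[, cc, drop = FALSE], abs_delta_min)
    out[[topic]] <- cbind(topic = topic, enr)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
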