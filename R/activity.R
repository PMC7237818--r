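# Gene-activity scores from region-cell accessibility probabilities.

#' Gene activity by TSS-window aggregation
#'
#' For each gene, sums the region-cell probabilities of all accessible regions
#' overlapping the union of (i) the 5 kb (configurable) window upstream of each
#' TSS — upstream in the biological sense, i.e. ending at the TSS on the `+`
#' strand and starting at it on the `-` strand — and (ii) the gene's introns.
#' Any overlap of at least 1 bp counts; each region is counted once per gene
#' even if it overlaps several windows. Genes with no overlapping region (or
#' on a chromosome absent from the region set, which raises a warning) get
#' all-zero rows.
#'
#' @param rc Region x cell matrix of accessibility probabilities.
#' @param regions Region table (`chrom`, `start`, `end`, `id`) matching the
#'   rows of `rc`.
#' @param genes A `gene_models` table.
#' @param upstream_bp Upstream window size in bp (default 5000).
#' @param include_introns Include intronic regions (default TRUE).
#' @return Gene x cell activity matrix.
#' @export
gene_activity_tss <- function(rc, regions, genes, upstream_bp = 5000,
                              include_introns = TRUE) {
  check_named_matrix(rc, "rc")
  check_regions(regions)
  if (!all(regions$id %in% rownames(rc)))
    stopf("region ids missing from rc rows")
  win <- gene_windows(genes, upstream_bp, include_introns)
  score_gene_windows(rc, regions, genes$gene_id, win)
}

# Build per-gene window tables: list of data.frames (chrom, start, end).
gene_windows <- function(genes, upstream_bp, include_introns) {
  lapply(seq_len(nrow(genes)), function(i) {
    strand <- genes$strand[i]
    tss <- genes$tss_list[[i]]
    if (strand == "+") {
      w <- cbind(start = pmax(tss - upstream_bp, 0L), end = tss)
    } else {
      w <- cbind(start = tss, end = tss + upstream_bp)
    }
    w <- w[w[, "end"] > w[, "start"], , drop = FALSE]
    if (include_introns && nrow(genes$introns[[i]]) > 0L)
      w <- rbind(w, genes$introns[[i]])
    data.frame(chrom = genes$chrom[i], start = w[, 1], end = w[, 2])
  })
}

# Sum rc rows of regions overlapping each gene's windows (>= 1 bp, half-open).
score_gene_windows <- function(rc, regions, gene_ids, windows) {
  out <- matrix(0, length(gene_ids), ncol(rc),
                dimnames = list(gene_ids, colnames(rc)))
  gr_regions <- regions_to_granges(regions)
  known_chroms <- unique(regions$chrom)
  win_df <- do.call(rbind, Map(function(w, g) {
    if (nrow(w) == 0L) return(NULL)
    cbind(w, gene = g)
  }, windows, gene_ids))
  if (is.null(win_df) || nrow(win_df) == 0L) return(out)
  unknown <- setdiff(unique(win_df$chrom), known_chroms)
  if (length(unknown) > 0) {
    warnf("gene chromosome(s) absent from region set: %s",
          paste(unknown, collapse = ", "))
    win_df <- win_df[win_df$chrom %in% known_chroms, , drop = FALSE]
    if (nrow(win_df) == 0L) return(out)
  }
  gr_win <- GenomicRanges::GRanges(win_df$chrom,
                                   IRanges::IRanges(win_df$start + 1L, win_df$end))
  hits <- GenomicRanges::findOverlaps(gr_win, gr_regions)
  if (length(hits) == 0L) return(out)
  pairs <- unique(data.frame(gene = win_df$gene[S4Vectors::queryHits(hits)],
                             region = regions$id[S4Vectors::subjectHits(hits)]))
  sums <- rowsum(rc[pairs$region, , drop = FALSE], group = pairs$gene, reorder = FALSE)
  out[rownames(sums), ] <- sums
  out
}

#' Gene activity from signed enhancer-to-gene links
#'
#' Aggregates region-cell probabilities over the regions linked to each gene,
#' weighting each region by its signed random-forest importance:
#' `score(g, c) = sum over links of sign * importance * rc(region, c)`.
#'
#' @param rc Region x cell accessibility matrix.
#' @param links A `link_table` (see [build_links()]) or a data.frame with
#'   columns `gene_id`, `region_id`, `rf_importance`, `sign`.
#' @return Gene x cell activity matrix.
#' @export
gene_activity_links <- function(rc, links) {
  if (inherits(links, "link_table")) links <- links$links
  need <- c("gene_id", "region_id", "rf_importance", "sign")
  if (!all(need %in% names(links)))
    stopf("links must have columns %s", paste(need, collapse = ", "))
  if (!all(links$region_id %in% rownames(rc)))
    stopf("link region(s) missing from rc rows")
  genes <- sort(unique(links$gene_id))
  out <- matrix(0, length(genes), ncol(rc), dimnames = list(genes, colnames(rc)))
  if (nrow(links) == 0L) return(out)
  weighted <- rc[links$region_id, , drop = FALSE] * (links$sign * links$rf_importance)
  sums <- rowsum(weighted, group = links$gene_id)
  out[rownames(sums), ] <- sums
  out
}
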