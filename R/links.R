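# Enhancer-to-gene link inference on virtual cells.
#
# Two complementary strategies are combined per gene over the candidate
# regions in its search space (+-window around one TSS, plus introns):
# (i) the Pearson correlation between region accessibility probability and
# gene expression across virtual cells, filtered at the 1st/99th percentiles
# of a normal distribution fitted to all correlations, and (ii) the
# variance-reduction importance of each region in a random-forest regression
# of expression on region accessibility, with the top regions per gene
# selected by step-function (BASC) binarization of the importances. A link is
# kept if either filter retains it (union), with provenance recorded, and is
# signed by the direction of its correlation.

#' Candidate regions in a gene's search space
#'
#' Regions overlapping the window `[tss - window_bp, tss + window_bp)` around
#' the gene's TSS, plus (optionally) its introns. Genes with several TSSs must
#' have one sampled beforehand (see [sample_tss()]); passing a multi-TSS gene
#' without `tss` is an error.
#'
#' @param gene One row of a `gene_models` table.
#' @param regions Region table.
#' @param window_bp Half-width of the search window (default 50000).
#' @param tss TSS to use; default the gene's only TSS.
#' @param include_introns Include intronic regions regardless of distance
#'   (default TRUE).
#' @return Character vector of region ids (empty, with a warning, when the
#'   gene's chromosome is absent from the region set).
#' @export
candidate_regions <- function(gene, regions, window_bp = 50000, tss = NULL,
                              include_introns = TRUE) {
  stopifnot(window_bp > 0)
  if (is.null(tss)) {
    if (length(gene$tss_list[[1]]) != 1L)
      stopf("gene %s has several TSSs; sample one first", gene$gene_id)
    tss <- gene$tss_list[[1]][1]
  }
  if (!gene$chrom %in% regions$chrom) {
    warnf("gene %s: chromosome '%s' absent from region set", gene$gene_id, gene$chrom)
    return(character(0))
  }
  win <- data.frame(chrom = gene$chrom, start = max(tss - window_bp, 0), end = tss + window_bp)
  if (include_introns && nrow(gene$introns[[1]]) > 0L)
    win <- rbind(win, data.frame(chrom = gene$chrom,
                                 start = gene$introns[[1]][, 1],
                                 end = gene$introns[[1]][, 2]))
  gr_win <- GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$start + 1L, win$end))
  hits <- GenomicRanges::findOverlaps(gr_win, regions_to_granges(regions))
  sort(unique(regions$id[S4Vectors::subjectHits(hits)]))
}

#' Sample one TSS per gene
#'
#' Genes with more than one annotated TSS get one position sampled uniformly,
#' once, before any per-gene computation; single-TSS genes keep theirs.
#'
#' @param genes A `gene_models` table.
#' @param seed Integer seed.
#' @return Named integer vector gene id -> TSS.
#' @export
sample_tss <- function(genes, seed = 1L) {
  withr::with_seed(seed, {
    vapply(seq_len(nrow(genes)), function(i) {
      tss <- genes$tss_list[[i]]
      if (length(tss) == 1L) tss else sample(tss, 1L)
    }, numeric(1)) -> out
    stats::setNames(as.integer(out), genes$gene_id)
  })
}

#' Pearson correlations between one gene and its candidate regions
#'
#' @param expr_row Numeric vector of expression over virtual cells.
#' @param rc_rows Region x virtual-cell matrix of accessibility probabilities
#'   (columns aligned with `expr_row`).
#' @return Named numeric vector of correlations. Correlations that are
#'   undefined because a vector is constant are reported as 0 and flagged in
#'   the `"constant"` attribute.
#' @export
link_correlations <- function(expr_row, rc_rows) {
  if (is.null(dim(rc_rows))) rc_rows <- matrix(rc_rows, nrow = 1)
  if (length(expr_row) != ncol(rc_rows)) stopf("length mismatch: expression vs regions")
  if (length(expr_row) < 3L) stopf("need at least 3 virtual cells")
  r <- suppressWarnings(as.vector(stats::cor(expr_row, t(rc_rows))))
  names(r) <- rownames(rc_rows)
  constant <- !is.finite(r)
  r[constant] <- 0
  attr(r, "constant") <- names(r)[constant]
  r
}

#' Correlation thresholds from a fitted normal
#'
#' Fits a normal distribution by maximum likelihood (mean and the 1/n-variance
#' standard deviation) to all correlations and returns its `lower_q` and
#' `upper_q` quantiles; with the defaults these are the 1st and 99th
#' percentiles, `mu +- 2.3263 * sigma`.
#'
#' @param all_r Numeric vector of correlations (>= 100 values).
#' @param lower_q,upper_q Quantiles (defaults 0.01 and 0.99).
#' @return Numeric `c(r_low, r_high)`.
#' @export
correlation_thresholds <- function(all_r, lower_q = 0.01, upper_q = 0.99) {
  all_r <- all_r[is.finite(all_r)]
  if (length(all_r) < 100L) stopf("need at least 100 correlations to fit thresholds")
  mu <- mean(all_r)
  sigma <- sqrt(mean((all_r - mu)^2))
  if (sigma == 0) stopf("zero variance: cannot fit thresholds")
  c(r_low = mu + stats::qnorm(lower_q) * sigma,
    r_high = mu + stats::qnorm(upper_q) * sigma)
}

#' Random-forest importances of candidate regions for one gene
#'
#' Fits a regression forest (variance-reduction split criterion,
#' `ceiling(sqrt(p))` candidate predictors per split) of gene expression on
#' the accessibility of the candidate regions and returns the per-region
#' impurity importance, normalized to sum to 1. Predictors are sorted by
#' region id before fitting, so the result does not depend on input order. A
#' constant response yields all-zero importances with a `"constant"` flag.
#'
#' @param expr_row Expression over virtual cells.
#' @param rc_rows Region x virtual-cell accessibility matrix (>= 2 regions,
#'   >= 10 cells).
#' @param n_trees Number of trees (default 1000).
#' @param seed Integer seed (forest is deterministic given the seed).
#' @return Named numeric vector of importances summing to 1 (or all zero).
#' @export
rf_importances <- function(expr_row, rc_rows, n_trees = 1000, seed = 1L) {
  if (is.null(dim(rc_rows)) || nrow(rc_rows) < 2L) stopf("need at least 2 candidate regions")
  if (ncol(rc_rows) < 10L) stopf("need at least 10 virtual cells")
  if (length(expr_row) != ncol(rc_rows)) stopf("length mismatch")
  rc_rows <- rc_rows[order(rownames(rc_rows)), , drop = FALSE]
  ids <- rownames(rc_rows)
  if (stats::var(expr_row) == 0) {
    out <- stats::setNames(rep(0, length(ids)), ids)
    attr(out, "constant") <- TRUE
    return(out)
  }
  x <- t(rc_rows)
  colnames(x) <- paste0("p", seq_len(ncol(x))) # syntactic names; order fixed above
  fit <- ranger::ranger(x = x, y = expr_row, num.trees = n_trees,
                        mtry = ceiling(sqrt(nrow(rc_rows))),
                        importance = "impurity", seed = seed, num.threads = 1)
  imp <- pmax(fit$variable.importance, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  stats::setNames(as.numeric(imp), ids)
}

#' Infer signed enhancer-to-gene links
#'
#' Runs the full linking stage over aligned virtual-cell expression and
#' accessibility matrices: one TSS per gene is sampled with the global seed;
#' per gene, candidate regions are collected and their correlations computed;
#' thresholds are fitted once to all correlations (constant-vector
#' correlations are excluded from the fit); random-forest importances are
#' computed per gene and binarized with [basc_binarize()]. A (gene, region)
#' pair is kept if it passes the correlation filter OR survives the per-gene
#' importance selection; `kept_by` records which. The sign is the sign of the
#' Pearson correlation.
#'
#' @param genes A `gene_models` table.
#' @param regions Region table matching the rows of `rc_virtual`.
#' @param expr_virtual Gene x virtual-cell expression matrix.
#' @param rc_virtual Region x virtual-cell accessibility matrix (same virtual
#'   cells as `expr_virtual`, any column order).
#' @param window_bp Search-space half-width (default 50000).
#' @param n_trees Trees per forest (default 1000).
#' @param lower_q,upper_q Correlation-threshold quantiles.
#' @param include_introns Include intronic regions in the search space.
#' @param min_cells_rf Minimum virtual cells to attempt the forest.
#' @param seed Global seed (stage seeds are derived from it).
#' @return A list of class `link_table`: `links` (data.frame with `gene_id`,
#'   `region_id`, `pearson_r`, `rf_importance`, `sign`, `kept_by`),
#'   `thresholds`, `params` (including the sampled TSSs), and `all_pairs`
#'   (the number of candidate pairs examined).
#' @export
build_links <- function(genes, regions, expr_virtual, rc_virtual,
                        window_bp = 50000, n_trees = 1000,
                        lower_q = 0.01, upper_q = 0.99,
                        include_introns = TRUE, min_cells_rf = 10, seed = 1L) {
  check_named_matrix(expr_virtual, "expr_virtual")
  check_named_matrix(rc_virtual, "rc_virtual")
  if (!setequal(colnames(expr_virtual), colnames(rc_virtual)))
    stopf("expression and accessibility matrices cover different virtual cells")
  # canonical virtual-cell order, so results do not depend on column order
  expr_virtual <- expr_virtual[, order(colnames(expr_virtual)), drop = FALSE]
  rc_virtual <- rc_virtual[, colnames(expr_virtual), drop = FALSE]
  tss <- sample_tss(genes, seed = derive_seed(seed, "tss"))

  cand <- list(); cors <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    if (!g %in% rownames(expr_virtual)) next
    ids <- candidate_regions(genes[i, , drop = FALSE], regions, window_bp,
                             tss = tss[[g]], include_introns = include_introns)
    ids <- ids[ids %in% rownames(rc_virtual)]
    if (length(ids) == 0L) next
    cand[[g]] <- ids
    cors[[g]] <- link_correlations(expr_virtual[g, ], rc_virtual[ids, , drop = FALSE])
  }
  all_r <- unlist(lapply(cors, function(r) r[!names(r) %in% attr(r, "constant")]),
                  use.names = FALSE)
  thr <- correlation_thresholds(all_r, lower_q, upper_q)

  rows <- list()
  for (g in names(cand)) {
    ids <- cand[[g]]
    r <- cors[[g]]
    corr_kept <- r < thr[["r_low"]] | r > thr[["r_high"]]
    imp <- stats::setNames(rep(NA_real_, length(ids)), ids)
    rf_kept <- stats::setNames(rep(FALSE, length(ids)), ids)
    if (length(ids) >= 2L && ncol(expr_virtual) >= min_cells_rf) {
      imp <- rf_importances(expr_virtual[g, ], rc_virtual[ids, , drop = FALSE],
                            n_trees = n_trees,
                            seed = derive_seed(seed, paste0("rf:", g)))
      if (length(ids) >= 3L && !isTRUE(attr(imp, "constant")) &&
          max(imp) - min(imp) > 0) {
        sel <- basc_binarize(imp)$selected
        rf_kept[sel] <- TRUE
      }
    }
    keep <- corr_kept | rf_kept
    if (!any(keep)) next
    kept_by <- ifelse(corr_kept & rf_kept, "correlation+rf",
                      ifelse(corr_kept, "correlation", "rf"))[keep]
    rows[[g]] <- data.frame(
      gene_id = g, region_id = ids[keep], pearson_r = unname(r[keep]),
      rf_importance = unname(imp[keep]),
      sign = ifelse(r[keep] >= 0, 1L, -1L), kept_by = kept_by
    )
  }
  links <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene_id = character(0), region_id = character(0),
               pearson_r = numeric(0), rf_importance = numeric(0),
               sign = integer(0), kept_by = character(0))
  rownames(links) <- NULL
  structure(list(links = links, thresholds = thr,
                 params = list(window_bp = window_bp, n_trees = n_trees,
                               seed = seed, tss = tss),
                 all_pairs = sum(lengths(cand))),
            class = "link_table")
}

#' Redundant (shadow) enhancer pairs per gene
#'
#' For each gene, all unordered pairs of its linked regions whose region-cell
#' accessibility profiles have Pearson correlation above `r_min` — highly
#' correlated enhancers linked to the same gene, i.e. candidate shadow
#' enhancers.
#'
#' @param links A `link_table` or its `links` data.frame.
#' @param rc_virtual Region x virtual-cell accessibility matrix.
#' @param r_min Correlation cutoff (default 0.8).
#' @return data.frame (`gene_id`, `region_a`, `region_b`, `r`).
#' @export
redundant_pairs <- function(links, rc_virtual, r_min = 0.8) {
  if (inherits(links, "link_table")) links <- links$links
  out <- list()
  for (g in unique(links$gene_id)) {
    ids <- sort(links$region_id[links$gene_id == g])
    if (length(ids) < 2L) next
    cm <- suppressWarnings(stats::cor(t(rc_virtual[ids, , drop = FALSE])))
    pr <- which(upper.tri(cm) & cm > r_min, arr.ind = TRUE)
    if (nrow(pr) == 0L) next
    out[[g]] <- data.frame(gene_id = g, region_a = ids[pr[, 1]],
                           region_b = ids[pr[, 2]], r = cm[pr])
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(0), region_a = character(0),
                      region_b = character(0), r = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distance-rank histogram of kept links
#'
#' For every kept link, the target gene is ranked among all genes by the
#' distance between the gene's TSS and the linked region's midpoint (genes on
#' other chromosomes rank after all same-chromosome genes; ties share the
#' minimum rank). Returns the histogram of these ranks; counts sum to the
#' number of links.
#'
#' @param links A `link_table` (its sampled TSSs are reused) or a data.frame
#'   plus an explicit `tss` vector.
#' @param genes A `gene_models` table.
#' @param regions Region table.
#' @param tss Optional named gene -> TSS vector; defaults to the link table's
#'   sampled TSSs, else each gene's first TSS.
#' @return data.frame (`rank`, `n_links`).
#' @export
link_distance_summary <- function(links, genes, regions, tss = NULL) {
  if (inherits(links, "link_table")) {
    tss <- tss %||% links$params$tss
    links <- links$links
  }
  if (is.null(tss))
    tss <- stats::setNames(vapply(genes$tss_list, `[`, numeric(1), 1), genes$gene_id)
  mid <- stats::setNames((regions$start + regions$end) / 2, regions$id)
  chrom_r <- stats::setNames(regions$chrom, regions$id)
  gchrom <- stats::setNames(genes$chrom, genes$gene_id)
  ranks <- vapply(seq_len(nrow(links)), function(i) {
    rid <- links$region_id[i]
    same <- names(gchrom)[gchrom == chrom_r[[rid]]]
    d <- abs(tss[same] - mid[[rid]])
    rank_all <- rank(d, ties.method = "min")
    g <- links$gene_id[i]
    if (g %in% same) unname(rank_all[g]) else length(same) + 1
  }, numeric(1))
  tab <- table(ranks)
  data.frame(rank = as.integer(names(tab)), n_links = as.integer(tab))
}
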