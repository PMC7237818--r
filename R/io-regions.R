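# Readers and writers for genomic regions (BED) and gene models.
#
# All coordinates are handled internally as 0-based half-open intervals (BED
# native). Nothing is ever shifted on read or write, so read/write pairs are
# exact round trips.

#' Read genomic regions from a BED file
#'
#' Parses a 3+ column tab-separated BED file into a region table with columns
#' `chrom`, `start`, `end`, `id`. Coordinates are kept 0-based half-open. The
#' id is taken from column 4 when present; otherwise it is synthesized as
#' `"chrom:start-end"`.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `id`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), id = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L) stopf("malformed BED line %d: fewer than 3 columns", i)
    start <- suppressWarnings(as.integer(p[2]))
    end <- suppressWarnings(as.integer(p[3]))
    if (is.na(start) || is.na(end))
      stopf("malformed BED line %d: non-integer coordinates", i)
    if (start >= end) stopf("malformed BED line %d: start >= end", i)
    id <- if (length(p) >= 4L && nzchar(p[4])) p[4] else sprintf("%s:%d-%d", p[1], start, end)
    out[[i]] <- data.frame(chrom = p[1], start = start, end = end, id = id)
  }
  regions <- do.call(rbind, out)
  rownames(regions) <- NULL
  check_regions(regions, "BED regions")
  regions
}

#' Write genomic regions to a BED file
#'
#' @param regions A region data.frame (`chrom`, `start`, `end`, `id`).
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  check_regions(regions)
  writeLines(sprintf("%s\t%d\t%d\t%s", regions$chrom, as.integer(regions$start),
                     as.integer(regions$end), regions$id), path)
  invisible(path)
}

#' Read gene models from a tab-separated file
#'
#' Expected columns: `gene_id`, `chrom`, `strand` (`+`/`-`), `tss`
#' (comma-separated 0-based positions) and `introns` (semicolon-separated
#' `start-end` half-open intervals; may be empty). Introns are sorted and must
#' be non-overlapping; every gene needs at least one TSS.
#'
#' @param path Path to the gene-model TSV.
#' @return A data.frame with list-columns `tss_list` (integer vectors) and
#'   `introns` (two-column matrices with columns `start`, `end`).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stopf("gene model file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "introns")
  if (!all(need %in% names(df)))
    stopf("gene model file must have columns %s", paste(need, collapse = ", "))
  gene_models(
    gene_id = df$gene_id, chrom = df$chrom, strand = df$strand,
    tss_list = lapply(strsplit(as.character(df$tss), ",", fixed = TRUE),
                      function(x) as.integer(x[nzchar(x)])),
    introns = lapply(as.character(df$introns), parse_introns)
  )
}

parse_introns <- function(s) {
  if (is.na(s) || !nzchar(s)) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- t(vapply(parts, function(p) as.integer(p[1:2]), integer(2)))
  colnames(m) <- c("start", "end")
  m[order(m[, 1]), , drop = FALSE]
}

#' Construct a validated gene-model table
#'
#' @param gene_id,chrom,strand Character vectors.
#' @param tss_list List of integer TSS vectors (at least one per gene).
#' @param introns List of two-column `start`/`end` matrices (0-based half-open,
#'   sorted, non-overlapping).
#' @return A data.frame of class `gene_models` with list-columns.
#' @export
gene_models <- function(gene_id, chrom, strand, tss_list, introns = NULL) {
  n <- length(gene_id)
  if (is.null(introns))
    introns <- rep(list(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))), n)
  stopifnot(length(chrom) == n, length(strand) == n, length(tss_list) == n,
            length(introns) == n)
  if (anyDuplicated(gene_id)) stopf("duplicate gene ids")
  if (!all(strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  for (i in seq_len(n)) {
    if (length(tss_list[[i]]) < 1L) stopf("gene %s has no TSS", gene_id[i])
    ivs <- introns[[i]]
    if (nrow(ivs) > 0L) {
      if (any(ivs[, 1] >= ivs[, 2])) stopf("gene %s: intron start >= end", gene_id[i])
      if (is.unsorted(ivs[, 1])) stopf("gene %s: introns not sorted", gene_id[i])
      if (nrow(ivs) > 1L && any(ivs[-1, 1] < ivs[-nrow(ivs), 2]))
        stopf("gene %s: overlapping introns", gene_id[i])
    }
  }
  out <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand)
  out$tss_list <- tss_list
  out$introns <- introns
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Write gene models to a tab-separated file
#'
#' @param genes A `gene_models` data.frame.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  tss <- vapply(genes$tss_list, function(x) paste(x, collapse = ","), character(1))
  introns <- vapply(genes$introns, function(m) {
    if (nrow(m) == 0L) "" else paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ";")
  }, character(1))
  df <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                   strand = genes$strand, tss = tss, introns = introns)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
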