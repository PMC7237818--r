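# Genotype matrices and VCF IO for the inbred-panel caQTL analysis.

#' Construct a genotype matrix
#'
#' @param snps data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `snp_id`.
#' @param values SNP x line matrix over `{0, 1, NA}` (0 = homozygous reference,
#'   1 = homozygous alternate, NA = unknown), rownames = snp ids, colnames =
#'   line ids.
#' @return A list of class `genotype_matrix`.
#' @export
genotype_matrix <- function(snps, values) {
  need <- c("chrom", "pos", "ref", "alt", "snp_id")
  if (!all(need %in% names(snps)))
    stopf("snps must have columns %s", paste(need, collapse = ", "))
  if (any(snps$ref == snps$alt)) stopf("ref and alt alleles must differ")
  if (anyDuplicated(snps$snp_id)) stopf("duplicate snp ids")
  values <- as.matrix(values)
  if (nrow(values) != nrow(snps)) stopf("values rows must match snps")
  if (!all(values %in% c(0, 1, NA))) stopf("genotype values must be 0, 1 or NA")
  rownames(values) <- snps$snp_id
  structure(list(snps = snps, values = values), class = "genotype_matrix")
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Parses a VCF 4.x file (via `vcfR`) and returns a binary genotype matrix for
#' the requested lines, following the inbred-panel coding: homozygous alternate
#' = 1 ("present"), homozygous reference = 0 ("absent"), heterozygous or
#' missing = NA ("unknown"). Multiallelic records are skipped (and counted);
#' indels are skipped by default. VCF POS (1-based) is converted to the
#' package-wide 0-based convention on read.
#'
#' @param path Path to the VCF file.
#' @param line_ids Lines (sample columns) to keep; default all. An id missing
#'   from the VCF header is an error.
#' @param snps_only Drop records whose REF or ALT is longer than 1 bp
#'   (default TRUE).
#' @return A `genotype_matrix`. The number of skipped records is attached as
#'   attribute `skipped`.
#' @export
read_vcf_biallelic <- function(path, line_ids = NULL, snps_only = TRUE) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  samples <- colnames(gt)[-1]
  if (is.null(line_ids)) line_ids <- samples
  missing <- setdiff(line_ids, samples)
  if (length(missing) > 0)
    stopf("line id(s) absent from VCF header: %s", paste(missing, collapse = ", "))

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  indel <- nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  keep <- !multi & (!snps_only | !indel)
  n_skip <- sum(!keep)
  if (n_skip > 0)
    message(sprintf("read_vcf_biallelic: skipped %d record(s) (%d multiallelic, %d non-SNP)",
                    n_skip, sum(multi), sum(indel & !multi)))
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  gt_fields <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
  gt_idx <- vapply(gt_fields, function(f) match("GT", f), integer(1))
  code_gt <- function(x, idx) {
    g <- mapply(function(parts, i) parts[i], strsplit(x, ":", fixed = TRUE), idx)
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0", "0")] <- 0
    out[g %in% c("1/1", "1")] <- 1
    out
  }
  vals <- matrix(NA_real_, nrow(fix), length(line_ids),
                 dimnames = list(NULL, line_ids))
  for (s in line_ids) vals[, s] <- code_gt(gt[, s], gt_idx)

  ids <- fix$ID
  no_id <- is.na(ids) | ids == "." | !nzchar(ids)
  ids[no_id] <- sprintf("%s:%s", fix$CHROM[no_id], fix$POS[no_id])
  snps <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
                     ref = fix$REF, alt = fix$ALT, snp_id = ids,
                     stringsAsFactors = FALSE)
  out <- genotype_matrix(snps, vals)
  attr(out, "skipped") <- n_skip
  out
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path.
#' @export
write_vcf <- function(geno, path) {
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                     "FORMAT", colnames(geno$values)), collapse = "\t"))
  gt_str <- matrix("./.", nrow(geno$values), ncol(geno$values))
  gt_str[!is.na(geno$values) & geno$values == 0] <- "0/0"
  gt_str[!is.na(geno$values) & geno$values == 1] <- "1/1"
  body <- vapply(seq_len(nrow(geno$snps)), function(i) {
    paste(c(geno$snps$chrom[i], geno$snps$pos[i] + 1L, geno$snps$snp_id[i],
            geno$snps$ref[i], geno$snps$alt[i], ".", "PASS", ".", "GT",
            gt_str[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
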