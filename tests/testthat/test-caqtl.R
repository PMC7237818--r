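test_that("CPM normalization scales per line only", {
  counts <- matrix(c(10, 20, 30, 40), 2,
                   dimnames = list(c("r1", "r2"), c("l1", "l2")))
  norm <- normalize_counts(counts)
  expect_equal(unname(colSums(norm)), c(1e6, 1e6))
  # doubling a line's counts leaves its CPM column unchanged
  counts2 <- counts
  counts2[, "l2"] <- counts2[, "l2"] * 2
  expect_equal(normalize_counts(counts2)[, "l2"], norm[, "l2"])
  # a million-read line is returned as-is
  one <- matrix(c(4e5, 6e5), 2, dimnames = list(c("r1", "r2"), "l1"))
  expect_equal(normalize_counts(one), one)
  zero <- counts
  zero[, 1] <- 0
  expect_error(normalize_counts(zero), "l1")
})

test_that("SNPs are assigned by half-open containment", {
  snps <- data.frame(chrom = "c", pos = c(150L, 200L, 99L, 120L),
                     ref = "A", alt = "C", snp_id = paste0("s", 1:4))
  geno <- genotype_matrix(snps, matrix(0, 4, 2,
                                       dimnames = list(snps$snp_id, c("l1", "l2"))))
  regions <- data.frame(chrom = "c", start = c(100L, 110L),
                        end = c(200L, 130L), id = c("rA", "rB"))
  asn <- assign_snps_to_regions(geno, regions)
  expect_true(all(c("s1", "s4") %in% asn$snp_id))
  expect_false("s2" %in% asn$snp_id) # pos == end excluded
  expect_false("s3" %in% asn$snp_id) # before start
  expect_equal(sum(asn$snp_id == "s4"), 2L) # overlapping regions: two pairs
})

test_that("the association scan recovers planted slopes and skips bad pairs", {
  set.seed(3)
  n <- 50
  g <- c(rep(0, 25), rep(1, 25))
  y <- 10 + 4 * g + rnorm(n, 0, 1)
  geno <- genotype_matrix(
    data.frame(chrom = "c", pos = c(5L, 15L), ref = "A", alt = "C",
               snp_id = c("hit", "mono")),
    rbind(hit = g, mono = rep(0, n)))
  colnames(geno$values) <- sprintf("l%02d", 1:n)
  acc <- rbind(rA = y, rB = rnorm(n))
  colnames(acc) <- colnames(geno$values)
  asn <- data.frame(snp_id = c("hit", "mono"), region_id = c("rA", "rB"))
  res <- caqtl_scan(acc, geno, asn)
  expect_equal(res$beta[1], 4, tolerance = 0.5)
  expect_true(res$caqtl[1])
  expect_equal(res$direction[1], "opening")
  expect_true(is.na(res$p[2])) # monomorphic skipped
  expect_equal(attr(res, "skipped"), 1L)
  expect_true(all(res$fdr >= res$p, na.rm = TRUE))
})

test_that("allele sequences place the accessible allele by the slope sign", {
  fasta <- list(chr1 = "AAAACGTAAAA")
  region <- data.frame(chrom = "chr1", start = 2L, end = 9L, id = "r")
  snp <- data.frame(chrom = "chr1", pos = 4L, ref = "C", alt = "G",
                    snp_id = "s")
  up <- allele_sequences(snp, region, fasta, beta = 2)
  expect_equal(up$seq_open, "AAGGTAA")   # alt allele open when beta > 0
  expect_equal(up$seq_closed, "AACGTAA")
  down <- allele_sequences(snp, region, fasta, beta = -2)
  expect_equal(down$seq_open, "AACGTAA") # ref allele open when beta < 0
  d <- mapply(function(a, b) a != b,
              strsplit(up$seq_open, "")[[1]], strsplit(up$seq_closed, "")[[1]])
  expect_equal(sum(d), 1L) # sequences differ at exactly one position
  snp_bad <- transform(snp, ref = "T")
  expect_error(allele_sequences(snp_bad, region, fasta, beta = 1), "mismatch")
})

test_that("motif scores match the consensus closed form and strand symmetry", {
  probs <- matrix(0.01, 8, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  cons <- c("A", "C", "G", "T", "T", "G", "C", "A")
  probs[cbind(1:8, match(cons, colnames(probs)))] <- 0.97
  p <- pwm("m", probs)
  cons_seq <- paste(cons, collapse = "")
  expect_equal(motif_best_score(cons_seq, p), 8 * log2(0.97 / 0.25))
  # reverse complement scores identically
  rc_seq <- chartr("ACGT", "TGCA", paste(rev(cons), collapse = ""))
  expect_equal(motif_best_score(rc_seq, p), motif_best_score(cons_seq, p))
  # flanking sequence never decreases the maximum
  expect_gte(motif_best_score(paste0("TTTT", cons_seq, "GGGG"), p),
             motif_best_score(cons_seq, p))
  # too-short sequence is flagged -Inf
  short <- motif_best_score("ACGT", p)
  expect_identical(unname(as.numeric(short)), -Inf)
  expect_true(attr(short, "too_short"))
  # windows containing N are excluded
  expect_identical(motif_best_score("ACGTNGCA", p), -Inf)
})

test_that("delta scores are antisymmetric and react to consensus disruption", {
  probs <- matrix(0.01, 8, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  cons <- c("A", "C", "G", "T", "A", "C", "G", "T")
  probs[cbind(1:8, match(cons, colnames(probs)))] <- 0.97
  pwms <- list(m = pwm("m", probs))
  open <- "TTACGTACGTTT"   # contains the consensus
  closed <- "TTACGAACGTTT" # SNP destroys it
  d <- delta_scores(open, closed, pwms)
  expect_gt(d$delta, 0)
  expect_equal(delta_scores(closed, open, pwms)$delta, -d$delta)
  expect_equal(d$delta, brute_best_score(open, pwms$m) -
                 brute_best_score(closed, pwms$m))
})

test_that("control selection and Fisher enrichment behave at the margins", {
  res <- data.frame(snp_id = paste0("s", 1:10), region_id = "r",
                    beta = 1, p = 0.5, fdr = c(rep(0.99, 6), rep(0.01, 4)),
                    direction = "opening", n_lines = 50,
                    caqtl = c(rep(FALSE, 6), rep(TRUE, 4)))
  picked <- select_control_snps(res, n = 3, seed = 2)
  expect_length(picked, 3)
  expect_true(all(picked %in% paste0("s", 1:6)))
  expect_equal(picked, select_control_snps(res, n = 3, seed = 2))
  expect_setequal(select_control_snps(res, n = 100, seed = 2), paste0("s", 1:6))
  all_sig <- transform(res, fdr = 0.01)
  expect_warning(none <- select_control_snps(all_sig), "empty control")
  expect_length(none, 0)

  # zero-margin table gives p = 1 by convention
  dc <- matrix(0, 2, 3, dimnames = list(c("m1", "m2"), paste0("q", 1:3)))
  ctrl <- matrix(0, 2, 4, dimnames = list(c("m1", "m2"), paste0("c", 1:4)))
  enr <- motif_enrichment(dc, ctrl)
  expect_true(all(enr$p == 1))
})
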