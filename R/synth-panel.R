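# Synthetic inbred-panel generator for the caQTL and motif-effect modules.
#
# Accessible regions are laid out on one synthetic chromosome with random
# background sequence. Each region carries one SNP. "Causal" SNPs sit inside
# a planted occurrence of the causal motif's consensus: the alternate allele
# destroys the consensus and reduces the region's read counts, so the caQTL
# slope is negative and the open (reference) allele carries the intact motif
# (positive delta score for the causal motif). "Off-motif" caQTLs change
# accessibility without touching any motif (random effect sign). The
# remaining SNPs have no effect and supply the control pool. Regions are
# partitioned into topics; all causal (motif-disrupting) SNPs fall in one
# topic, so per-topic enrichment should localize there.

#' Specification of a synthetic caQTL panel
#'
#' @param n_lines Inbred lines (default 50).
#' @param n_causal Regions with a consensus-disrupting caQTL (default 40;
#'   all placed in topic 2).
#' @param n_offmotif Regions with a motif-free caQTL (default 20; split over
#'   the other topics).
#' @param n_null Regions with a no-effect SNP (default 300).
#' @param region_len Region length in bp (default 150).
#' @param motif_len Motif length (default 8).
#' @param n_decoy_motifs Decoy motifs scored alongside the causal one.
#' @param consensus_p Per-position consensus probability of every PWM.
#' @param effect Relative accessibility effect per alternate allele (the
#'   causal direction is closing; off-motif effects get random signs).
#' @param base_cpm Range of per-region baseline accessibility (CPM units).
#' @param depth Range of per-line sequencing depths (reads).
#' @param maf Alternate-allele frequency across lines.
#' @param na_rate Fraction of genotype calls set to unknown (NA).
#' @param n_topics Number of region topics (default 3).
#' @param seed Integer seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_lines = 50, n_causal = 40, n_offmotif = 20,
                       n_null = 300, region_len = 150, motif_len = 8,
                       n_decoy_motifs = 50, consensus_p = 0.97, effect = 0.5,
                       base_cpm = c(50, 150), depth = c(8e5, 1.2e6),
                       maf = 0.5, na_rate = 0.02, n_topics = 3, seed = 1L) {
  if (motif_len >= region_len) stopf("motif longer than region")
  structure(as.list(environment()), class = "panel_spec")
}

consensus_pwm <- function(motif_id, consensus, p) {
  bases <- c("A", "C", "G", "T")
  idx <- match(strsplit(consensus, "", fixed = TRUE)[[1]], bases)
  probs <- matrix((1 - p) / 3, length(idx), 4, dimnames = list(NULL, bases))
  probs[cbind(seq_along(idx), idx)] <- p
  pwm(motif_id, probs)
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Generate a synthetic caQTL panel bundle
#'
#' @param spec A [panel_spec()].
#' @return A list of class `panel_bundle` with components `counts` (region x
#'   line integer matrix), `genotypes` (a `genotype_matrix`), `regions`,
#'   `fasta` (named chromosome sequences), `pwms` (causal motif `M_causal`
#'   plus decoys), `topics` (named list topic -> region ids) and `truth`
#'   (per-SNP class, topic and effect sign; the causal consensus).
#' @export
make_caqtl_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  withr::with_seed(spec$seed, {
    bases <- c("A", "C", "G", "T")
    n_regions <- spec$n_causal + spec$n_offmotif + spec$n_null
    gap <- 100L
    starts <- 100L + (seq_len(n_regions) - 1L) * (spec$region_len + gap)
    regions <- data.frame(chrom = "chrP", start = starts,
                          end = starts + spec$region_len,
                          id = sprintf("pr%04d", seq_len(n_regions)))
    genome_len <- max(regions$end) + 100L
    genome <- sample(bases, genome_len, replace = TRUE)

    ## region classes and topics
    class <- c(rep("causal", spec$n_causal), rep("offmotif", spec$n_offmotif),
               rep("null", spec$n_null))
    topic <- integer(n_regions)
    topic[class == "causal"] <- 2L
    other_topics <- setdiff(seq_len(spec$n_topics), 2L)
    topic[class == "offmotif"] <- rep_len(other_topics, spec$n_offmotif)
    topic[class == "null"] <- rep_len(seq_len(spec$n_topics), spec$n_null)

    ## motifs: causal consensus + decoys (all distinct, no revcomp clashes)
    draw_consensus <- function() paste(sample(bases, spec$motif_len, replace = TRUE),
                                       collapse = "")
    consensus <- draw_consensus()
    seen <- c(consensus, revcomp_str(consensus))
    decoys <- character(0)
    while (length(decoys) < spec$n_decoy_motifs) {
      cand <- draw_consensus()
      if (cand %in% seen) next
      seen <- c(seen, cand, revcomp_str(cand))
      decoys <- c(decoys, cand)
    }
    pwms <- c(list(M_causal = consensus_pwm("M_causal", consensus, spec$consensus_p)),
              stats::setNames(
                lapply(seq_along(decoys), function(i)
                  consensus_pwm(sprintf("M_decoy%02d", i), decoys[i],
                                spec$consensus_p)),
                sprintf("M_decoy%02d", seq_along(decoys))))

    ## plant motifs and SNPs; build genotype matrix
    motif_off <- 60L      # consensus start within a causal region (0-based)
    snp_in_motif <- 3L    # SNP at consensus position 4
    plain_off <- 30L      # SNP position within off-motif/null regions
    snp_rows <- list()
    gvals <- matrix(NA_real_, n_regions, spec$n_lines,
                    dimnames = list(NULL, sprintf("line%02d", seq_len(spec$n_lines))))
    effect_mult <- matrix(1, n_regions, spec$n_lines)
    effect_sign <- rep(0L, n_regions)
    cons_chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
    for (i in seq_len(n_regions)) {
      if (class[i] == "causal") {
        pos0 <- regions$start[i] + motif_off
        genome[(pos0 + 1L):(pos0 + spec$motif_len)] <- cons_chars
        snp_pos <- pos0 + snp_in_motif
        ref <- cons_chars[snp_in_motif + 1L]
        alt <- sample(setdiff(bases, ref), 1L)
        effect_sign[i] <- -1L # alternate allele destroys the motif and closes
      } else {
        snp_pos <- regions$start[i] + plain_off
        ref <- genome[snp_pos + 1L]
        alt <- sample(setdiff(bases, ref), 1L)
        effect_sign[i] <- if (class[i] == "offmotif") sample(c(-1L, 1L), 1L) else 0L
      }
      repeat {
        g <- stats::rbinom(spec$n_lines, 1L, spec$maf)
        if (spec$na_rate > 0)
          g[stats::runif(spec$n_lines) < spec$na_rate] <- NA
        n1 <- sum(g == 1, na.rm = TRUE)
        n0 <- sum(g == 0, na.rm = TRUE)
        if (n1 >= 5 && n0 >= 5) break
      }
      gvals[i, ] <- g
      gnum <- ifelse(is.na(g), 0, g)
      effect_mult[i, ] <- pmax(1 + effect_sign[i] * spec$effect * gnum, 0.05)
      snp_rows[[i]] <- data.frame(chrom = "chrP", pos = snp_pos, ref = ref,
                                  alt = alt, snp_id = sprintf("snp%04d", i))
    }
    snps <- do.call(rbind, snp_rows)
    genotypes <- genotype_matrix(snps, gvals)

    ## counts: Poisson around depth-scaled CPM with mild per-entry noise
    base <- stats::runif(n_regions, spec$base_cpm[1], spec$base_cpm[2])
    depth <- stats::runif(spec$n_lines, spec$depth[1], spec$depth[2])
    mu <- outer(base, depth / 1e6) * effect_mult *
      matrix(exp(stats::rnorm(n_regions * spec$n_lines, 0, 0.05)), n_regions)
    counts <- matrix(stats::rpois(length(mu), mu), n_regions,
                     dimnames = list(regions$id, colnames(gvals)))

    structure(list(
      spec = spec,
      counts = counts,
      genotypes = genotypes,
      regions = regions,
      fasta = stats::setNames(list(paste(genome, collapse = "")), "chrP"),
      pwms = pwms,
      topics = stats::setNames(
        lapply(seq_len(spec$n_topics), function(t) regions$id[topic == t]),
        sprintf("topic%d", seq_len(spec$n_topics))),
      truth = list(
        snps = data.frame(snp_id = snps$snp_id, region_id = regions$id,
                          class = class, topic = sprintf("topic%d", topic),
                          effect_sign = effect_sign),
        causal_motif = "M_causal", consensus = consensus)
    ), class = "panel_bundle")
  })
}

#' Write a panel bundle to a directory in standard formats
#'
#' Counts TSV, VCF, FASTA genome, Cluster-Buster-style motif file, region
#' BED, topic membership TSV, and the truth table.
#'
#' @param bundle A `panel_bundle`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_panel <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  storage.mode(bundle$counts) <- "double"
  write_matrix(bundle$counts, p("counts.tsv"))
  write_vcf(bundle$genotypes, p("panel.vcf"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(bundle$fasta)), p("genome.fa"))
  write_pwms(bundle$pwms, p("motifs.cb"))
  write_bed(bundle$regions, p("regions.bed"))
  topics_df <- do.call(rbind, lapply(names(bundle$topics), function(t)
    data.frame(topic = t, region_id = bundle$topics[[t]])))
  utils::write.table(topics_df, p("topics.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$truth$snps, p("truth_snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run the full caQTL stage on a panel bundle
#'
#' Normalization, SNP-region assignment, association scan, control selection,
#' delta scores for caQTLs and controls, bulk motif enrichment and per-topic
#' enrichment.
#'
#' @param bundle A `panel_bundle` (or an equivalent list built from files).
#' @param fdr_max caQTL threshold (default 0.05).
#' @param n_controls Control SNPs to sample (default 50).
#' @param control_fdr_min Control eligibility threshold (default 0.95).
#' @param abs_delta_min |delta| cutoff for the enrichment test (default 3).
#' @param seed Seed for the control sample.
#' @return list(`scan`, `controls`, `deltas_caqtl`, `deltas_control`,
#'   `enrichment`, `per_topic`).
#' @export
caqtl_pipeline <- function(bundle, fdr_max = 0.05, n_controls = 50,
                           control_fdr_min = 0.95, abs_delta_min = 3,
                           seed = 1L) {
  norm <- normalize_counts(bundle$counts)
  assignment <- assign_snps_to_regions(bundle$genotypes, bundle$regions)
  scan <- caqtl_scan(norm, bundle$genotypes, assignment, fdr_max = fdr_max)
  controls <- select_control_snps(scan, fdr_min = control_fdr_min,
                                  n = n_controls,
                                  seed = derive_seed(seed, "controls"))
  caqtl_tab <- scan[scan$caqtl, c("snp_id", "region_id", "beta")]
  ctrl_tab <- scan[scan$snp_id %in% controls, c("snp_id", "region_id", "beta")]
  deltas_caqtl <- delta_matrix(caqtl_tab, bundle$genotypes, bundle$regions,
                               bundle$fasta, bundle$pwms)
  deltas_control <- delta_matrix(ctrl_tab, bundle$genotypes, bundle$regions,
                                 bundle$fasta, bundle$pwms)
  enrichment <- motif_enrichment(deltas_caqtl, deltas_control, abs_delta_min)
  per_topic <- per_topic_enrichment(
    deltas_caqtl, deltas_control,
    stats::setNames(caqtl_tab$region_id, caqtl_tab$snp_id),
    stats::setNames(ctrl_tab$region_id, ctrl_tab$snp_id),
    bundle$topics, abs_delta_min)
  list(scan = scan, controls = controls, deltas_caqtl = deltas_caqtl,
       deltas_control = deltas_control, enrichment = enrichment,
       per_topic = per_topic)
}
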