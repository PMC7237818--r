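test_that("tissue bundles are deterministic and internally consistent", {
  sp <- tissue_spec(n_cells_per_type = 60, n_genes = 6, n_pos_links = 2,
                    n_neg_links = 2, n_decoys_per_gene = 3, n_specific = 2,
                    n_primed = 2, seed = 99)
  b1 <- make_tissue(sp)
  b2 <- make_tissue(sp)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_tissue(b1, d1); write_tissue(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # topic factors are column-stochastic and the product is a distribution
  m <- b1$atac$model
  expect_lt(max(abs(colSums(m$region_topic) - 1)), 1e-9)
  expect_lt(max(abs(colSums(m$topic_cell) - 1)), 1e-9)
  expect_true(all(m$region_topic >= 0) && all(m$topic_cell >= 0))
  expect_lt(max(abs(colSums(predictive_distribution(m)) - 1)), 1e-9)
  # planted regions sit in their gene's search space
  tss <- vapply(b1$genes$tss_list, `[`, numeric(1), 1)
  names(tss) <- b1$genes$gene_id
  for (i in seq_len(nrow(b1$truth$links))) {
    reg <- b1$regions[b1$regions$id == b1$truth$links$region_id[i], ]
    expect_lt(abs((reg$start + reg$end) / 2 - tss[b1$truth$links$gene_id[i]]),
              50000)
  }
})

test_that("noise-free planted links are near-perfectly correlated at the true u", {
  b <- make_tissue(tissue_spec(n_cells_per_type = 200, noise_sd = 0,
                               dropout = 0, seed = 5))
  rc <- predictive_distribution(b$atac$model)
  u <- b$truth$u_atac
  ct <- setNames(b$atac$cells$cell_type, b$atac$cells$cell_id)
  tl <- b$truth$links
  for (i in seq_len(nrow(tl))) {
    expr_true <- profile_at(b, tl$gene_id[i], u, ct[names(u)])
    r <- cor(expr_true, rc[tl$region_id[i], names(u)])
    expect_gt(abs(r), 0.99)
    expect_equal(sign(r), tl$sign[i])
  }
})

test_that("full dropout warns and zeroes expression", {
  expect_warning(
    b <- make_tissue(tissue_spec(n_cells_per_type = 20, n_genes = 3,
                                 n_pos_links = 1, n_neg_links = 1,
                                 n_decoys_per_gene = 2, n_specific = 1,
                                 n_primed = 1, dropout = 1, seed = 1)),
    "dropout")
  expect_true(all(b$rna$expression == 0))
})

test_that("panel bundles are deterministic with motif-disrupting causal SNPs", {
  sp <- panel_spec(n_causal = 6, n_offmotif = 3, n_null = 20,
                   n_decoy_motifs = 5, seed = 77)
  b1 <- make_caqtl_panel(sp)
  b2 <- make_caqtl_panel(sp)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_panel(b1, d1); write_panel(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # causal SNP: open (reference) allele carries the consensus -> delta > 0
  truth <- b1$truth$snps
  causal <- truth[truth$class == "causal", ]
  for (i in seq_len(nrow(causal))) {
    snp <- b1$genotypes$snps[b1$genotypes$snps$snp_id == causal$snp_id[i], ]
    region <- b1$regions[b1$regions$id == causal$region_id[i], ]
    seqs <- allele_sequences(snp, region, b1$fasta, beta = -1)
    d <- delta_scores(seqs$seq_open, seqs$seq_closed,
                      b1$pwms["M_causal"])
    expect_gt(d$delta, 3)
  }
  # zero effect everywhere keeps calls near the FDR expectation
  b0 <- make_caqtl_panel(panel_spec(n_causal = 0, n_offmotif = 0, n_null = 150,
                                    n_decoy_motifs = 3, seed = 11))
  sc <- caqtl_scan(normalize_counts(b0$counts), b0$genotypes,
                   assign_snps_to_regions(b0$genotypes, b0$regions))
  expect_lte(sum(sc$caqtl), 10)
})
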