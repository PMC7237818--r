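test_that("candidate search space is the TSS window plus introns", {
  regions <- data.frame(
    chrom = "chr1",
    start = c(60000L, 151000L, 400000L, 90000L),
    end = c(60500L, 151500L, 400500L, 90500L),
    id = c("in_window", "past_window", "intronic", "near")
  )
  gene <- gene_models("g", "chr1", "+", list(100000L),
                      list(matrix(c(399000L, 401000L), 1, 2,
                                  dimnames = list(NULL, c("start", "end")))))
  ids <- candidate_regions(gene, regions, window_bp = 50000)
  expect_true("in_window" %in% ids)  # within -50 kb
  expect_true("near" %in% ids)
  expect_false("past_window" %in% ids) # past +50 kb and not intronic
  expect_true("intronic" %in% ids)     # intron 300 kb away still included
  ids2 <- candidate_regions(gene, regions, window_bp = 50000,
                            include_introns = FALSE)
  expect_false("intronic" %in% ids2)

  gx <- gene_models("gx", "chrZ", "+", list(100000L))
  expect_warning(out <- candidate_regions(gx, regions), "absent")
  expect_length(out, 0)
})

test_that("multi-TSS genes get one seeded TSS sampled up front", {
  genes <- gene_models(c("a", "b"), c("c", "c"), c("+", "+"),
                       list(c(10L, 500L, 900L), 50L))
  t1 <- sample_tss(genes, seed = 5)
  expect_equal(t1, sample_tss(genes, seed = 5))
  expect_true(t1[["a"]] %in% c(10L, 500L, 900L))
  expect_equal(t1[["b"]], 50L)
  expect_error(candidate_regions(genes[1, ],
                                 data.frame(chrom = "c", start = 1L, end = 2L,
                                            id = "r")),
               "several TSSs")
})

test_that("link correlations handle perfect, inverse and constant signals", {
  x <- c(1, 2, 3, 4, 5)
  rc <- rbind(same = x, inv = -x + 10, lin = 2 * x, const = rep(1, 5))
  r <- link_correlations(x, rc)
  expect_equal(unname(r["same"]), 1)
  expect_equal(unname(r["inv"]), -1)
  expect_equal(unname(r["lin"]), 1)
  expect_equal(unname(r["const"]), 0)
  expect_equal(attr(r, "constant"), "const")
  expect_error(link_correlations(x[1:3], rc), "mismatch")
})

test_that("threshold fitting recovers the generating normal and is equivariant", {
  set.seed(11)
  r <- rnorm(1e4, 0, 0.1)
  thr <- correlation_thresholds(r)
  expect_equal(unname(thr["r_low"]), qnorm(0.01, 0, 0.1), tolerance = 0.03)
  expect_equal(unname(thr["r_high"]), qnorm(0.99, 0, 0.1), tolerance = 0.03)
  thr_shift <- correlation_thresholds(r + 0.3)
  expect_equal(unname(thr_shift - thr), c(0.3, 0.3), tolerance = 1e-12)
  expect_error(correlation_thresholds(rnorm(50)), "at least 100")
  expect_error(correlation_thresholds(rep(0.5, 200)), "zero variance")
})

test_that("forest importances recover a planted predictor and ignore order", {
  set.seed(2)
  n <- 300
  signal <- rnorm(n)
  rc <- rbind(sig = signal, matrix(rnorm(4 * n), 4,
                                   dimnames = list(paste0("noise", 1:4), NULL)))
  colnames(rc) <- paste0("c", seq_len(n))
  wins <- 0L
  for (s in 1:20) {
    imp <- rf_importances(signal, rc, n_trees = 300, seed = s)
    if (names(which.max(imp)) == "sig") wins <- wins + 1L
  }
  expect_gte(wins, 19L)

  imp1 <- rf_importances(signal, rc, n_trees = 200, seed = 4)
  imp2 <- rf_importances(signal, rc[c(3, 1, 5, 2, 4), ], n_trees = 200, seed = 4)
  expect_equal(imp1, imp2)
  expect_equal(sum(imp1), 1)

  imp0 <- rf_importances(rep(1, n), rc, n_trees = 50, seed = 1)
  expect_true(all(imp0 == 0))
  expect_true(attr(imp0, "constant"))
})

test_that("kept links carry the correlation sign and survive cell shuffles", {
  b <- make_tissue(tissue_spec(n_cells_per_type = 80, n_genes = 12,
                               n_pos_links = 4, n_neg_links = 4,
                               n_decoys_per_gene = 8, seed = 13))
  rc <- predictive_distribution(b$atac$model)
  # truth-pair by latent rank so both matrices share virtual cells
  ord_r <- ord_a <- character(0)
  for (ty in unique(b$rna$cells$cell_type)) {
    r <- b$rna$cells[b$rna$cells$cell_type == ty, ]
    a <- b$atac$cells[b$atac$cells$cell_type == ty, ]
    ord_r <- c(ord_r, r$cell_id[order(r$u)])
    ord_a <- c(ord_a, a$cell_id[order(a$u)])
  }
  expr_v <- b$rna$expression[, ord_r]
  rc_v <- rc[, ord_a]
  colnames(expr_v) <- colnames(rc_v) <- sprintf("v%03d", seq_along(ord_r))
  lt <- build_links(b$genes, b$regions, expr_v, rc_v, n_trees = 200, seed = 3)
  expect_gt(nrow(lt$links), 0)
  nz <- lt$links$pearson_r != 0
  expect_equal(lt$links$sign[nz], ifelse(lt$links$pearson_r[nz] > 0, 1L, -1L))
  expect_false(anyDuplicated(paste(lt$links$gene_id, lt$links$region_id)) > 0)
  expect_true(all(lt$links$kept_by %in% c("correlation", "rf", "correlation+rf")))

  # shuffling virtual cells identically in both matrices changes nothing
  perm <- sample(ncol(expr_v))
  lt2 <- build_links(b$genes, b$regions, expr_v[, perm], rc_v[, perm],
                     n_trees = 200, seed = 3)
  expect_equal(lt2$links, lt$links)
})

test_that("redundant pairs require linked regions with correlated profiles", {
  rc <- rbind(r1 = c(1, 2, 3, 4), r2 = c(2, 4, 6, 8), r3 = c(4, 3, 2, 1))
  colnames(rc) <- paste0("v", 1:4)
  links <- data.frame(gene_id = c("g", "g", "g", "h"),
                      region_id = c("r1", "r2", "r3", "r1"),
                      rf_importance = 1, sign = 1L)
  rp <- redundant_pairs(links, rc, r_min = 0.8)
  expect_equal(nrow(rp), 1L) # only the r1-r2 duplicate pair
  expect_setequal(c(rp$region_a, rp$region_b), c("r1", "r2"))
  expect_equal(nrow(redundant_pairs(links[4, ], rc)), 0L) # single link
  expect_equal(nrow(redundant_pairs(links, rc, r_min = 1.0)), 0L)
})

test_that("distance-rank histogram conserves the number of links", {
  genes <- gene_models(c("g1", "g2", "g3"), rep("c", 3), rep("+", 3),
                       list(1000L, 5000L, 9000L))
  regions <- data.frame(chrom = "c", start = c(1100L, 5100L),
                        end = c(1200L, 5200L), id = c("rA", "rB"))
  links <- data.frame(gene_id = c("g1", "g2", "g3"),
                      region_id = c("rA", "rB", "rB"),
                      rf_importance = 1, sign = 1L)
  h <- link_distance_summary(links, genes, regions)
  expect_equal(sum(h$n_links), nrow(links))
  expect_equal(h$n_links[h$rank == 1], 2L) # rA->g1 and rB->g2 are nearest
  # single-gene genome: every link ranks first
  h1 <- link_distance_summary(links[1, ], genes[1, ], regions)
  expect_equal(h1, data.frame(rank = 1L, n_links = 1L))
})
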