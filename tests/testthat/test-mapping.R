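test_that("diffusion pseudotime orders a noiseless 1-D trajectory", {
  set.seed(1)
  pos <- sort(runif(80, 0, 10))
  emb <- cbind(pos, 0, 0)
  rownames(emb) <- sprintf("c%03d", 1:80)
  pt <- diffusion_pseudotime(emb, root_cell = "c001", k_neighbors = 10)
  expect_equal(unname(pt["c001"]), 0)
  expect_true(all(pt >= 0))
  expect_equal(cor(pt, pos, method = "spearman"), 1)

  # permuting the input rows leaves the values unchanged
  perm <- sample(nrow(emb))
  pt2 <- diffusion_pseudotime(emb[perm, ], root_cell = "c001", k_neighbors = 10)
  expect_equal(pt2[names(pt)], pt, tolerance = 1e-8)

  # disconnected graph is reported
  emb2 <- rbind(emb, matrix(1000 + runif(30), 10, 3,
                            dimnames = list(sprintf("far%02d", 1:10), NULL)))
  expect_error(diffusion_pseudotime(emb2, "c001", k_neighbors = 5),
               "disconnected")
})

test_that("real-cell binning matches the virtual contract", {
  pt <- setNames(runif(30), sprintf("c%02d", 1:30))
  ct <- setNames(rep("t", 30), names(pt))
  rb <- bin_real(pt, ct, n_bins = 10)
  expect_equal(as.vector(table(rb$bin)), rep(3L, 10))
  # bin index non-decreasing along pseudotime
  ord <- order(pt[rb$cell_id])
  expect_true(all(diff(rb$bin[ord]) >= 0))
  expect_warning(bin_real(pt[1:4], ct[1:4], n_bins = 10), "fewer")
})

test_that("cell assignment respects pool sizes, coverage and the seed", {
  vb <- data.frame(vcell_id = sprintf("v%02d", 1:5), cell_type = "t", bin = 1L)
  rb5 <- data.frame(cell_id = sprintf("r%02d", 1:5), cell_type = "t", bin = 1L)
  m <- assign_cells(vb, rb5, seed = 3)
  expect_setequal(m$cell_id, rb5$cell_id) # bijection when sizes match

  rb2 <- data.frame(cell_id = c("r1", "r2"), cell_type = "t", bin = 1L)
  m2 <- assign_cells(vb, rb2, seed = 3)
  expect_equal(nrow(m2), 5L)
  expect_true(all(table(m2$cell_id) >= 1)) # every real cell used at least once

  expect_equal(assign_cells(vb, rb5, seed = 9), assign_cells(vb, rb5, seed = 9))

  # empty bin falls back to the whole-type pool with a warning
  vb2 <- data.frame(vcell_id = c("v1", "v2"), cell_type = "t", bin = c(1L, 2L))
  rb3 <- data.frame(cell_id = c("r1", "r2"), cell_type = "t", bin = 1L)
  expect_warning(m3 <- assign_cells(vb2, rb3, seed = 1), "whole-type pool")
  expect_equal(nrow(m3), 2L)

  # missing cell type errors
  vbx <- data.frame(vcell_id = "v1", cell_type = "nope", bin = 1L)
  expect_error(assign_cells(vbx, rb5, seed = 1), "absent from real data")

  # non-spatial types are matched type-wide
  vbn <- data.frame(vcell_id = c("v1", "v2", "v3"), cell_type = "glia",
                    bin = NA_integer_)
  rbn <- data.frame(cell_id = c("g1", "g2", "g3", "g4"), cell_type = "glia",
                    bin = NA_integer_)
  mn <- assign_cells(vbn, rbn, seed = 2)
  expect_equal(nrow(mn), 3L)
  expect_false(anyDuplicated(mn$cell_id) > 0)
})

test_that("per-bin usage is uniform across seeds", {
  vb <- data.frame(vcell_id = sprintf("v%d", 1:6), cell_type = "t", bin = 1L)
  rb <- data.frame(cell_id = c("rA", "rB", "rC"), cell_type = "t", bin = 1L)
  usage <- integer(3)
  names(usage) <- rb$cell_id
  for (s in 1:300) {
    m <- assign_cells(vb, rb, seed = s)
    tab <- table(m$cell_id)
    usage[names(tab)] <- usage[names(tab)] + as.integer(tab)
  }
  expect_gt(chisq.test(usage)$p.value, 0.01)
})

test_that("projection copies columns exactly", {
  mat <- matrix(rnorm(12), 3, dimnames = list(NULL, c("r1", "r2", "r3", "r4")))
  mapping <- structure(data.frame(vcell_id = c("v1", "v2", "v3"),
                                  cell_id = c("r2", "r2", "r4")),
                       class = c("cell_mapping", "data.frame"))
  out <- project(mapping, mat)
  expect_equal(unname(out[, "v1"]), unname(mat[, "r2"]))
  expect_equal(out[, "v1"], out[, "v2"], ignore_attr = TRUE) # duplicated column
  expect_equal(unname(out[, "v3"]), unname(mat[, "r4"]))
  # a row of ones stays a row of ones
  ones <- matrix(1, 1, 4, dimnames = list("one", colnames(mat)))
  expect_true(all(project(mapping, ones) == 1))
  bad <- mapping
  bad$cell_id[1] <- "missing"
  expect_error(project(bad, mat), "missing")
})
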