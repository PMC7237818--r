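test_that("label grids become virtual cells with pixel coordinates", {
  grid <- matrix(0L, 3, 3)
  grid[1, 1] <- 1L; grid[2, 3] <- 1L; grid[3, 2] <- 2L; grid[3, 3] <- 2L
  tpl <- template_from_label_grid(grid, c(`1` = "a", `2` = "b"))
  expect_equal(nrow(tpl$cells), 4L)
  expect_equal(sort(unique(tpl$cells$cell_type)), c("a", "b"))
  expect_equal(tpl$cells$x[tpl$cells$y == 2], 3) # (col, row) convention
  expect_false(anyDuplicated(tpl$cells$vcell_id) > 0)

  empty <- template_from_label_grid(matrix(0L, 3, 3), c(`1` = "a"))
  expect_equal(nrow(empty$cells), 0L)
  expect_error(template_from_label_grid(grid, c(`1` = "a")), "without cell-type")
})

test_that("compartments are seeded discs inside their radius", {
  tpl <- tiny_template()
  n0 <- nrow(tpl$cells)
  g1 <- add_compartment(tpl, "glia", center = c(20, 20), radius = 3,
                        n_cells = 10, seed = 42)
  expect_equal(nrow(g1$cells), n0 + 10L)
  added <- g1$cells[g1$cells$cell_type == "glia", ]
  expect_true(all(sqrt((added$x - 20)^2 + (added$y - 20)^2) <= 3))
  expect_false(any(added$spatial))
  g2 <- add_compartment(tpl, "glia", center = c(20, 20), radius = 3,
                        n_cells = 10, seed = 42)
  expect_equal(g1$cells, g2$cells)
})

test_that("interleaving alternates labels with at most one count difference", {
  grid <- matrix(0L, 1, 11)
  grid[1, 1:6] <- 1L; grid[1, 7:11] <- 2L
  tpl <- template_from_label_grid(grid, c(`1` = "pr", `2` = "int"))
  out <- interleave_types(tpl, "pr", "int", axis = "x")
  counts <- table(out$cells$cell_type)
  expect_lte(abs(diff(as.integer(counts))), 1L)
  # deterministic alternation along x
  ord <- order(out$cells$x)
  expect_equal(out$cells$cell_type[ord],
               rep_len(c("pr", "int"), nrow(out$cells)))
  expect_error(interleave_types(tpl, "pr", "nope"), "absent")
})

test_that("landmark distances follow the axis and radial definitions", {
  tpl <- tiny_template()
  d <- landmark_distances(tpl)
  expect_equal(unname(d["v03"]), 3) # x = 3, line at x0 = 0
  expect_equal(unname(d["v07"]), sqrt(1 + 1)) # (10,5) vs (11,6)
  # cell on the reference line
  tpl2 <- tiny_template()
  tpl2$landmarks[[1]] <- landmark("stripe", "axis_x", x0 = 1, direction = "increasing")
  expect_equal(unname(landmark_distances(tpl2)["v01"]), 0)
  # radial distances are translation invariant
  tpl3 <- tiny_template()
  tpl3$cells$x <- tpl3$cells$x + 100
  tpl3$cells$y <- tpl3$cells$y - 7
  tpl3$landmarks[[2]] <- landmark("ring", "radial", x0 = 111, y0 = -1,
                                  direction = "increasing")
  tpl3$landmarks[[1]] <- landmark("stripe", "axis_x", x0 = 100, direction = "increasing")
  d3 <- landmark_distances(tpl3)
  ring <- sprintf("v%02d", 7:10)
  expect_equal(d3[ring], d[ring])
  # uncovered spatial type errors
  tpl4 <- tiny_template()
  tpl4$landmarks <- tpl4$landmarks[1]
  expect_error(landmark_distances(tpl4), "without landmark")
})

test_that("virtual binning is equal-count with stable ties and orientation", {
  cells <- data.frame(vcell_id = sprintf("v%02d", 1:20), x = 1:20, y = 0,
                      cell_type = "t", spatial = TRUE)
  tpl <- virtual_template(cells, list(landmark("t", "axis_x", x0 = 0,
                                               direction = "increasing")))
  d <- landmark_distances(tpl)
  vb <- bin_virtual(tpl, d, n_bins = 10)
  expect_equal(as.vector(table(vb$bin)), rep(2L, 10))
  expect_equal(vb$bin[vb$vcell_id == "v01"], 1L) # closest to reference = bin 1

  # decreasing direction flips the orientation
  tpl$landmarks[[1]] <- landmark("t", "axis_x", x0 = 0, direction = "decreasing")
  vb2 <- bin_virtual(tpl, d, n_bins = 10)
  expect_equal(vb2$bin[vb2$vcell_id == "v01"], 10L)

  # 21 cells: sizes differ by at most one
  cells21 <- rbind(cells, data.frame(vcell_id = "v21", x = 21, y = 0,
                                     cell_type = "t", spatial = TRUE))
  tpl21 <- virtual_template(cells21, list(landmark("t", "axis_x", x0 = 0,
                                                   direction = "increasing")))
  vb21 <- bin_virtual(tpl21, landmark_distances(tpl21), n_bins = 10)
  expect_true(all(table(vb21$bin) %in% 2:3))

  # all-equal distances: stable id order, still balanced
  cells_t <- transform(cells, x = 5)
  tpl_t <- virtual_template(cells_t, list(landmark("t", "axis_x", x0 = 0,
                                                   direction = "increasing")))
  vb_t <- bin_virtual(tpl_t, landmark_distances(tpl_t), n_bins = 10)
  expect_equal(as.vector(table(vb_t$bin)), rep(2L, 10))
  expect_equal(vb_t$bin[order(vb_t$vcell_id)], rep(1:10, each = 2))

  # fewer cells than bins collapses with a warning
  tpl_s <- virtual_template(cells[1:3, ], list(landmark("t", "axis_x", x0 = 0,
                                                        direction = "increasing")))
  expect_warning(vb_s <- bin_virtual(tpl_s, landmark_distances(tpl_s), 10),
                 "fewer")
  expect_equal(sort(vb_s$bin), 1:3)
})
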