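make_model <- function() {
  rt <- matrix(c(0.7, 0.3, 0.2, 0.8), 2,
               dimnames = list(c("r1", "r2"), c("t1", "t2")))
  tc <- matrix(c(0.5, 0.5, 1, 0, 0.25, 0.75), 2,
               dimnames = list(c("t1", "t2"), c("c1", "c2", "c3")))
  topic_model(rt, tc)
}

test_that("predictive distribution is the stochastic matrix product", {
  m <- make_model()
  rc <- predictive_distribution(m)
  expect_equal(unname(rc[, "c1"]), c(0.45, 0.55)) # hand product
  expect_equal(unname(colSums(rc)), rep(1, 3), tolerance = 1e-9)

  # rank-1: one topic copies its region column to every cell
  rt1 <- matrix(c(0.6, 0.4), 2, dimnames = list(c("r1", "r2"), "t1"))
  tc1 <- matrix(1, 1, 3, dimnames = list("t1", c("c1", "c2", "c3")))
  rc1 <- predictive_distribution(topic_model(rt1, tc1))
  expect_true(all(rc1 == c(0.6, 0.4)))

  bad <- m
  rownames(bad$topic_cell) <- c("t1", "tX")
  expect_error(topic_model(bad$region_topic, bad$topic_cell), "topic ids")
})

test_that("topic binarization keeps the top tail, monotone in the threshold", {
  rt <- matrix(c(0.999, 0.0006, 0.0004,
                 1 / 3, 1 / 3, 1 / 3), 3,
               dimnames = list(c("ra", "rb", "rc"), c("t1", "t2")))
  tc <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("t1", "t2"), "c1"))
  m <- topic_model(rt, tc)
  b <- binarize_topics(m, 0.985)
  expect_equal(b$t1, "ra") # single dominant region selected
  expect_equal(length(binarize_topics(m, 1.0)$t1), 0L) # threshold 1 -> empty

  # lowering the threshold never removes a selected region
  prev <- character(0)
  for (thr in c(0.999, 0.9, 0.7, 0.5, 0.2)) {
    cur <- binarize_topics(m, thr)$t2
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("TSS-window gene activity is strand-aware and additive", {
  rc <- matrix(c(1, 2, 3, 10, 20, 30, 100, 200, 300), 3, byrow = TRUE,
               dimnames = list(c("rA", "rB", "rC"), c("c1", "c2", "c3")))
  regions <- data.frame(chrom = "chr1",
                        start = c(6000L, 9000L, 11000L),
                        end = c(6500L, 9500L, 11500L),
                        id = c("rA", "rB", "rC"))
  # + strand at 10000: window [5000, 10000) -> rA, rB
  gplus <- gene_models("gp", "chr1", "+", list(10000L))
  # - strand at 10000: window [10000, 15000) -> rC only
  gminus <- gene_models("gm", "chr1", "-", list(10000L))
  act_p <- gene_activity_tss(rc, regions, gplus)
  act_m <- gene_activity_tss(rc, regions, gminus)
  expect_equal(unname(act_p["gp", ]), unname(rc["rA", ] + rc["rB", ]))
  expect_equal(unname(act_m["gm", ]), unname(rc["rC", ]))

  # single overlapping region -> row equals that region's row
  g1 <- gene_models("g1", "chr1", "+", list(6600L))
  expect_equal(unname(gene_activity_tss(rc, regions, g1)["g1", ]),
               unname(rc["rA", ]))

  # unknown chromosome -> warning + zero row
  gx <- gene_models("gx", "chrZ", "+", list(10000L))
  expect_warning(act_x <- gene_activity_tss(rc, regions, gx), "chrZ")
  expect_true(all(act_x == 0))

  # region order invariance
  act_r <- gene_activity_tss(rc[c(3, 1, 2), ], regions[c(2, 3, 1), ], gplus)
  expect_equal(act_r, act_p)
})

test_that("link-weighted gene activity is linear and signed", {
  rc <- matrix(c(1, 2, 3, 4, 5, 6), 2, byrow = TRUE,
               dimnames = list(c("rA", "rB"), c("c1", "c2", "c3")))
  links1 <- data.frame(gene_id = "g", region_id = "rA",
                       rf_importance = 1, sign = 1L)
  expect_equal(unname(gene_activity_links(rc, links1)["g", ]), unname(rc["rA", ]))

  # equal-importance positive + negative on identical rows cancel
  rc2 <- rbind(rc, rB2 = rc["rA", ])
  links2 <- data.frame(gene_id = "g", region_id = c("rA", "rB2"),
                       rf_importance = 0.5, sign = c(1L, -1L))
  expect_true(all(gene_activity_links(rc2, links2) == 0))

  # doubling importances doubles scores
  links3 <- data.frame(gene_id = "g", region_id = c("rA", "rB"),
                       rf_importance = c(0.3, 0.7), sign = c(1L, -1L))
  links3b <- transform(links3, rf_importance = 2 * rf_importance)
  expect_equal(gene_activity_links(rc, links3b),
               2 * gene_activity_links(rc, links3))
})
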