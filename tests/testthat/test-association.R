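fake_assoc_inputs <- function(p, log2r, set = "set-I") {
  n <- length(p)
  ids <- sprintf("t%02d", seq_len(n))
  screen <- tibble::tibble(
    transcript_id = ids,
    p_ir_g1_gt_g2 = p, p_ir_g2_gt_g1 = 1 - p,
    p_ir_two_sided = pmin(1, 2 * pmin(p, 1 - p)))
  sets <- tibble::tibble(transcript_id = ids, ir_set = set,
                         expr_subset = "A", set_label = paste0(set, "A"))
  ir_summary <- tibble::tibble(transcript_id = ids, log2_ratio = log2r)
  list(screen = screen, sets = sets, ir = ir_summary)
}

test_that("top-N selection ranks by p with deterministic tie-breaks", {
  x <- fake_assoc_inputs(p = c(0.001, 0.004, 0.002, 0.03, 0.01),
                         log2r = c(1, 1, 1, 1, 1))
  top <- select_top_n(x$screen, x$sets, x$ir, n = 3)
  expect_equal(top$transcript_id, c("t01", "t03", "t02"))
  expect_equal(top$rank, 1:3)
  # n larger than the set returns everything
  expect_equal(nrow(select_top_n(x$screen, x$sets, x$ir, n = 200)), 5L)
  # equal p: order by |log2_ratio| descending, then id
  y <- fake_assoc_inputs(p = rep(0.01, 4), log2r = c(0.5, 2, -3, 2))
  top_y <- select_top_n(y$screen, y$sets, y$ir, n = 4)
  expect_equal(top_y$transcript_id, c("t03", "t02", "t04", "t01"))
  # empty source set warns and returns empty
  expect_warning(
    empty <- select_top_n(x$screen, x$sets, x$ir, source_set = "set-II"),
    "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("Z scoring standardises rows and respects the given orders", {
  tpm <- mat_to_tpm(matrix(c(1, 2, 3,
                             5, 5, 5), 2, byrow = TRUE,
                           dimnames = list(c("a", "b"), c("s1", "s2", "s3"))))
  z <- zscore_rows(tpm, c("b", "a"), c("s3", "s1", "s2"))
  expect_equal(z$transcript_id, c("b", "a"))
  expect_equal(names(z), c("transcript_id", "s3", "s1", "s2"))
  expect_equal(unlist(z[z$transcript_id == "a", -1], use.names = FALSE),
               c(1, -1, 0))          # (3,1,2) standardised, sd = 1
  expect_equal(unlist(z[z$transcript_id == "b", -1], use.names = FALSE),
               c(0, 0, 0))           # constant row rule
  # input row order never affects output column order
  z2 <- zscore_rows(tpm[sample(nrow(tpm)), ], c("b", "a"), c("s3", "s1", "s2"))
  expect_equal(z2, z)
  expect_error(zscore_rows(tpm, "a", c("s1", "nope")), "Unknown sample")
  # property: random matrices give mean 0 / sd 1 on non-constant rows
  set.seed(8)
  m <- matrix(rlnorm(60), 6, dimnames = list(sprintf("r%d", 1:6),
                                             sprintf("c%d", 1:10)))
  zr <- zscore_rows(mat_to_tpm(m), sprintf("r%d", 1:6), sprintf("c%d", 1:10))
  vals <- as.matrix(zr[, -1])
  expect_equal(unname(rowMeans(vals)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(vals, 1, sd)), rep(1, 6), tolerance = 1e-9)
})

test_that("sample ordering places controls first, then subgroup blocks", {
  md <- tibble::tibble(
    sample = c("c1", "c2", "u1", "m1", "u2", "m2"),
    group = c("NBC", "NBC", "CLL", "CLL", "CLL", "CLL"),
    subgroup = c(NA, NA, "U-CLL", "M-CLL", "U-CLL", "M-CLL"))
  expect_equal(sample_block_order(md, control = "NBC"),
               c("c1", "c2", "m1", "m2", "u1", "u2"))
})

test_that("volcano coordinates and quadrants follow the group summaries", {
  # construct TPMs with exactly known group medians of the ratio
  gm <- two_group_map(3, 3)
  ex <- mat_to_tpm(matrix(10, 2, 6, dimnames = list(c("up", "flat"),
                                                    gm$sample)), "exonic")
  im <- matrix(10, 2, 6, dimnames = list(c("up", "flat"), gm$sample))
  im["up", 1:3] <- 40      # group1 ratio 4, group2 ratio 1
  intr <- mat_to_tpm(im, "intronic")
  ir <- compute_ir(ex, intr, gm, epsilon = 0)
  tx <- mat_to_tpm(matrix(c(30, 30, 30, 10, 10, 10,
                            10, 10, 10, 10, 10, 10), 2, byrow = TRUE,
                          dimnames = list(c("up", "flat"), gm$sample)))
  scr <- ir_screen(intr, tx, gm, group1 = "CLL")
  v <- volcano_table(ir, scr, tx)
  expect_equal(v$x[v$transcript_id == "up"], 2)       # log2(4/1)
  expect_equal(v$x[v$transcript_id == "flat"], 0)
  expect_equal(v$quadrant[v$transcript_id == "up"],
               "more IR, higher expression in group1")
  expect_equal(v$quadrant[v$transcript_id == "flat"], "boundary")
  expect_s3_class(plot_volcano(v), "ggplot")

  # brute-force oracle for x on random data
  set.seed(30)
  m_ex <- matrix(rlnorm(5 * 6), 5, dimnames = list(sprintf("t%d", 1:5),
                                                   gm$sample))
  m_in <- matrix(rlnorm(5 * 6), 5, dimnames = list(sprintf("t%d", 1:5),
                                                   gm$sample))
  ir2 <- compute_ir(mat_to_tpm(m_ex, "exonic"), mat_to_tpm(m_in, "intronic"),
                    gm, epsilon = 0.01)
  manual_x <- vapply(1:5, function(i) {
    r <- (m_in[i, ] + 0.01) / (m_ex[i, ] + 0.01)
    log2(median(r[1:3]) / median(r[4:6]))
  }, numeric(1))
  expect_equal(
    ir2$summary$log2_ratio[match(sprintf("t%d", 1:5),
                                 ir2$summary$transcript_id)],
    manual_x, tolerance = 1e-12)
})

test_that("quadrant counts compare group summaries pointwise and conserve totals", {
  mk_ir <- function(g1, g2) {
    structure(list(summary = tibble::tibble(
      transcript_id = sprintf("t%d", seq_along(g1)),
      summary_g1 = g1, summary_g2 = g2, log2_ratio = log2(g1 / g2))),
      class = "ir_table")
  }
  qc <- quadrant_counts(mk_ir(c(2, 3, 1, 1), c(1, 1, 2, 1)))
  expect_equal(qc$above, 2L)
  expect_equal(qc$below, 1L)
  expect_equal(qc$on, 1L)
  expect_equal(qc$above + qc$on + qc$below, qc$n)
  expect_equal(qc$pct_above, 67)  # 2 of 3 off-diagonal
  # all equal
  qc0 <- quadrant_counts(mk_ir(c(1, 1), c(1, 1)))
  expect_equal(c(qc0$above, qc0$below), c(0L, 0L))
  # swapping groups exchanges above and below
  qswap <- quadrant_counts(mk_ir(c(1, 1, 2, 1), c(2, 3, 1, 1)))
  expect_equal(c(qswap$above, qswap$below), c(qc$below, qc$above))
})
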