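two_group_design <- function(n_per = 2) {
  tibble::tibble(
    sample_id = c(sprintf("L%d", seq_len(n_per)), sprintf("H%d", seq_len(n_per))),
    group = rep(c("L", "H"), each = n_per)
  )
}

test_that("normalize_cpm scales every sample to a common total", {
  design <- two_group_design(2)
  counts <- tibble::tibble(feature_id = c("f1", "f2"),
                           L1 = c(10, 999990), L2 = c(20, 1999980),
                           H1 = c(10, 999990), H2 = c(10, 99990))
  norm <- normalize_cpm(counts, design)
  m <- expr_matrix(norm$expr)
  expect_equal(unname(colSums(m)), rep(1e6, 4))
  # proportional libraries give equal normalized values
  expect_equal(m["f1", "L1"], m["f1", "L2"])

  counts$L1 <- c(0, 0)
  expect_error(normalize_cpm(counts, design), "zero total")
})

test_that("log2_fold_change reproduces printed table rows with fitted scale", {
  # miRNA table row: means 35074 / 7418 at c = 1.36775 -> printed -1.78953
  expect_equal(log2_fold_change(35074, 7418, scale = 1.36775), -1.78953,
               tolerance = 1e-4)
  # lncRNA table row: 79374.24 / 168343.7 at c = 1.0938 -> printed 1.213923
  expect_equal(log2_fold_change(79374.24, 168343.7, scale = 1.0938), 1.213923,
               tolerance = 1e-4)
  expect_equal(log2_fold_change(123, 123), 0)
  expect_error(log2_fold_change(0, 10), "positive")
})

test_that("fit_scale_constant recovers the implied per-table constants", {
  # identity calibration when printed log2fc is the plain ratio
  rows <- tibble::tibble(mean_L = c(10, 20), mean_H = c(40, 10),
                         log2fc = log2(c(4, 0.5)))
  expect_equal(fit_scale_constant(rows), 1)

  mirna <- fc_reference("miRNA")
  expect_equal(fit_scale_constant(mirna[-1, ]), 1.368, tolerance = 1e-3)
  lnc <- fc_reference("lncRNA")
  expect_equal(fit_scale_constant(lnc[-1, ]), 1.094, tolerance = 1e-3)
  expect_error(fit_scale_constant(mirna[0, ]), "at least one")
})

test_that("de_test is a two-sided pooled binomial z-test", {
  expect_equal(de_test(50, 50, 1e6, 1e6), 1, tolerance = 1e-12)
  # 400 vs 100 with equal totals: z = (0.8 - 0.5) / sqrt(0.25 / 500)
  z <- 0.3 / sqrt(0.25 / 500)
  expect_equal(de_test(100, 400, 1e6, 1e6), 2 * pnorm(-z), tolerance = 1e-12)
  # more evidence at the same proportion cannot raise the p-value
  expect_lte(de_test(200, 800, 2e6, 2e6), de_test(100, 400, 1e6, 1e6))
  expect_equal(de_test(0, 0, 1e6, 1e6), 1)
  expect_error(de_test(-1, 5, 10, 10), "non-negative")
})

test_that("bh_adjust matches hand-computed and naive-oracle values", {
  expect_equal(bh_adjust(c(0.001, 0.01, 0.03)), c(0.003, 0.015, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  set.seed(99)
  for (rep in 1:20) {
    p <- runif(sample(5:60, 1))
    expect_equal(bh_adjust(p), naive_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("call_de gates are inclusive and threshold-monotone", {
  res <- tibble::tibble(log2fc = c(1, 0.99, -3), q = c(0.001, 1e-9, 0.0011))
  out <- call_de(res)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  expect_equal(out$direction, c("Up", "none", "none"))

  # idempotent and monotone in q_threshold
  expect_identical(call_de(out), out)
  relaxed <- call_de(res, q_threshold = 0.01)
  expect_true(all(out$significant <= relaxed$significant))
})

test_that("diff_expression produces coherent DE tables", {
  set.seed(1)
  design <- two_group_design(6)
  n <- 60
  counts <- tibble::tibble(feature_id = sprintf("f%03d", 1:n))
  base <- rlnorm(n, log(400), 0.4)
  shift <- rep(1, n)
  shift[1:6] <- 4      # planted up
  shift[7:12] <- 0.25  # planted down
  for (s in design$sample_id) {
    mu <- if (startsWith(s, "H")) base * shift else base
    counts[[s]] <- rpois(n, mu)
  }
  de <- diff_expression(counts, design)
  expect_s3_class(de, "cx_de")
  expect_true(all(de$q >= de$p))
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_true(all(de$direction[1:6] == "Up"))
  expect_true(all(de$direction[7:12] == "Down"))
  expect_true(mean(de$significant[13:n]) <= 0.05)

  g <- glance(de)
  expect_equal(g$n_significant, sum(de$significant))
  expect_equal(nrow(tidy(de)), n)
  expect_s3_class(autoplot(de), "ggplot")
})

test_that("gene-level aggregation sums transcript counts before testing", {
  design <- two_group_design(2)
  counts <- tibble::tibble(feature_id = c("t1", "t2", "t3"),
                           L1 = c(10, 20, 5), L2 = c(12, 18, 5),
                           H1 = c(40, 80, 5), H2 = c(44, 76, 5))
  by_gene <- c(t1 = "gA", t2 = "gA", t3 = "gB")
  de <- diff_expression(counts, design, by_gene = by_gene)
  expect_setequal(de$feature_id, c("gA", "gB"))
  direct <- diff_expression(
    tibble::tibble(feature_id = c("gA", "gB"),
                   L1 = c(30, 5), L2 = c(30, 5), H1 = c(120, 5), H2 = c(120, 5)),
    design
  )
  expect_equal(de$p[match("gA", de$feature_id)],
               direct$p[match("gA", direct$feature_id)])
})

test_that("fpkm_bins partitions features by the printed boundaries", {
  design <- two_group_design(1)
  expr <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                         L1 = c(0.5, 1.0, 5, 10), H1 = c(0, 0, 0, 0))
  attr(expr, "unit") <- "FPKM"
  bins <- fpkm_bins(expr)
  expect_equal(unlist(bins[bins$sample_id == "L1", c("low", "mid", "high")],
                      use.names = FALSE),
               c(2, 1, 1))
  expect_equal(unlist(bins[bins$sample_id == "H1", c("low", "mid", "high")],
                      use.names = FALSE),
               c(4, 0, 0))
  # partition property on random FPKM
  set.seed(3)
  rnd <- tibble::tibble(feature_id = sprintf("f%d", 1:50),
                        L1 = rlnorm(50), H1 = rlnorm(50, 2))
  attr(rnd, "unit") <- "FPKM"
  b <- fpkm_bins(rnd)
  expect_true(all(b$low + b$mid + b$high == 50))

  attr(rnd, "unit") <- "count"
  expect_error(fpkm_bins(rnd), "FPKM")
})

test_that("fpkm normalizes by length and library size", {
  design <- two_group_design(1)
  counts <- tibble::tibble(feature_id = c("a", "b"), L1 = c(100, 900), H1 = c(1, 999))
  out <- fpkm(counts, c(a = 1000, b = 2000))
  # a: 100 * 1e9 / (1000 * 1000) = 1e5
  expect_equal(out$L1[1], 1e5)
  expect_equal(attr(out, "unit"), "FPKM")
})
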