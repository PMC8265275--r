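rec <- function(chrom, start, end, strand, id = "x") {
  tibble::tibble(transcript_id = id, gene_id = id, chrom = chrom,
                 strand = strand, start = start, end = end)
}

test_that("classify_relation handles the window rule and strand reflection", {
  mrna <- rec("chr1", 100000, 110000, "+")
  out <- classify_relation(rec("chr1", 95000, 98000, "+"), mrna)
  expect_equal(out$relation, "upstream")
  expect_equal(out$distance, 2000)

  out <- classify_relation(rec("chr1", 60000, 89999, "+"), mrna)
  expect_equal(out$relation, "none")
  expect_equal(out$distance, 10001)

  # 5' of a minus-strand gene lies to its right
  mrna_neg <- rec("chr1", 100000, 110000, "-")
  out <- classify_relation(rec("chr1", 110001, 112000, "+"), mrna_neg)
  expect_equal(out$relation, "upstream")
  expect_equal(out$distance, 1)

  # boundary inclusivity: gap exactly 10,000 upstream is still cis
  out <- classify_relation(rec("chr1", 80000, 90000, "+"), mrna)
  expect_equal(out$relation, "upstream")
  expect_equal(out$distance, 10000)

  # overlap vs anti-overlap by strand equality
  expect_equal(classify_relation(rec("chr1", 105000, 106000, "+"), mrna)$relation,
               "overlap")
  expect_equal(classify_relation(rec("chr1", 105000, 106000, "-"), mrna)$relation,
               "anti-overlap")
  expect_equal(classify_relation(rec("chr2", 100000, 101000, "+"), mrna)$relation,
               "none")
  expect_error(classify_relation(rec("chr1", 1, 2, "*"), mrna), "strand")
})

test_that("classify_relation agrees with the brute-force case oracle", {
  set.seed(21)
  n <- 2000
  lnc <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE, prob = c(0.9, 0.1)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    start = sample.int(60000, n)
  )
  lnc$end <- lnc$start + sample.int(15000, n)
  mrna <- tibble::tibble(
    chrom = "chr1",
    strand = sample(c("+", "-"), n, replace = TRUE),
    start = sample.int(60000, n)
  )
  mrna$end <- mrna$start + sample.int(15000, n)
  got <- classify_relation(lnc, mrna)
  for (i in seq_len(n)) {
    want <- brute_relation(lnc$chrom[i], lnc$start[i], lnc$end[i], lnc$strand[i],
                           mrna$chrom[i], mrna$start[i], mrna$end[i], mrna$strand[i])
    expect_equal(got$relation[i], want$relation)
    expect_equal(got$distance[i], want$distance)
  }
  # total function: every pair maps to exactly one defined relation
  expect_true(all(got$relation %in%
                    c("upstream", "downstream", "overlap", "anti-overlap", "none")))
})

test_that("expression_correlation computes Pearson and Spearman with ties", {
  out <- expression_correlation(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(out$pearson, 1)
  expect_equal(out$spearman, 1)

  out <- expression_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(out$pearson, 0.8)
  expect_equal(out$spearman, 0.8)

  out <- expression_correlation(c(1, 2, 3), c(3, 2, 1))
  expect_equal(out$pearson, -1)
  expect_equal(out$spearman, -1)

  expect_error(expression_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(expression_correlation(1:2, 1:2), "length")

  # agreement with a naive two-pass reference on random vectors
  set.seed(8)
  for (rep in 1:20) {
    x <- rnorm(12)
    y <- rnorm(12)
    got <- expression_correlation(x, y)
    naive_p <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got$pearson, naive_p, tolerance = 1e-12)
    d <- rank(x) - rank(y)
    expect_equal(got$spearman, 1 - 6 * sum(d^2) / (12 * (144 - 1)),
                 tolerance = 1e-12)
  }
})

test_that("trans_candidate applies the windowed duplex rule", {
  set.seed(31)
  mrna <- rand_rna(120, alphabet = c("G", "C"))
  lnc <- paste0(rand_rna(40), cernaxis:::rna_revcomp(substr(mrna, 41, 80)),
                rand_rna(40))
  out <- trans_candidate(lnc, mrna)
  expect_lt(out$min_mfe, -30)
  expect_true(out$is_trans)

  out <- trans_candidate(strrep("A", 100), strrep("A", 100))
  expect_equal(out$min_mfe, 0)
  expect_false(out$is_trans)

  # coarse stride can only miss minima: stride-20 result bounds stride-1
  s1 <- rand_rna(120)
  s2 <- rand_rna(120)
  coarse <- trans_candidate(s1, s2, window = 40, step = 20)$min_mfe
  fine <- trans_candidate(s1, s2, window = 40, step = 1)$min_mfe
  expect_gte(coarse, fine)

  expect_error(trans_candidate("ACGU", "ACGU"), "at least")
})

test_that("build_cis_pairs recovers planted neighbors and applies both gates", {
  set.seed(77)
  ann <- dplyr::bind_rows(
    dplyr::mutate(rec("chr1", 100000, 110000, "+", "geneA"), biotype = "mRNA",
                  novel = FALSE),
    dplyr::mutate(rec("chr1", 95000, 97000, "+", "lnc_good"), biotype = "lncRNA",
                  novel = FALSE),
    dplyr::mutate(rec("chr1", 112000, 114000, "+", "lnc_uncorr"), biotype = "lncRNA",
                  novel = FALSE),
    dplyr::mutate(rec("chr1", 500000, 502000, "+", "lnc_far"), biotype = "lncRNA",
                  novel = FALSE)
  )
  samples <- sprintf("s%02d", 1:12)
  base <- rlnorm(12, log(100), 0.8)
  expr <- tibble::tibble(feature_id = c("geneA", "lnc_good", "lnc_uncorr", "lnc_far"))
  m <- rbind(base,
             base * rlnorm(12, 0, 0.1),
             rlnorm(12, log(100), 0.8),
             base * rlnorm(12, 0, 0.1))
  colnames(m) <- samples
  expr <- dplyr::bind_cols(expr, tibble::as_tibble(m))
  de_stub <- function(ids, sig) {
    tibble::tibble(feature_id = ids, log2fc = 2, q = 0,
                   significant = sig, direction = ifelse(sig, "Up", "none"))
  }
  de_lnc <- de_stub(c("lnc_good", "lnc_uncorr", "lnc_far"), TRUE)
  de_mrna <- de_stub("geneA", TRUE)
  pairs <- build_cis_pairs(ann, expr, de_lnc, de_mrna)
  expect_equal(pairs$lnc_id, "lnc_good")
  expect_equal(pairs$relation, "upstream")
  expect_true(pairs$mrna_is_de)
  expect_gte(pairs$pearson, 0.6)
})
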