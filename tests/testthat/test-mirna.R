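mir24 <- "UGGCUCAGUUCAGCAGGAACAG" # miR-24-3p, 22 nt
# deterministic 30-nt fragment carrying the validated wild-type heptamer
wild_fragment <- paste0("AAACCAAACCA", "CUGAGCU", "AACCAAACCAAA")
mut_fragment <- sub("CUGAGCU", "GCACAUC", wild_fragment, fixed = TRUE)

test_that("align_score matches the closed-form perfect-duplex value", {
  set.seed(4)
  m <- rand_rna(22)
  res <- align_score(m, cernaxis:::rna_revcomp(m))
  expect_equal(res$score, 7 * 5 * 4 + 15 * 5) # 215
  expect_equal(nrow(res$pairs), 22L)
  expect_true(all(res$pairs$kind == "WC"))

  expect_equal(align_score(strrep("A", 22), strrep("A", 30))$score, 0)
  expect_error(align_score("ACGU", strrep("A", 30)), "18-26")
})

test_that("align_score is invariant to swapping the roles of a perfect duplex", {
  set.seed(14)
  for (rep in 1:5) {
    m <- rand_rna(22)
    rc <- cernaxis:::rna_revcomp(m)
    expect_equal(align_score(m, rc)$score, align_score(rc, m)$score)
  }
})

test_that("miR-24-3p pairs its wild-type site across positions 2-8 with one G:U", {
  res <- align_score(mir24, wild_fragment)
  seed_pairs <- res$pairs[res$pairs$mirna_pos %in% 2:8, ]
  expect_setequal(seed_pairs$mirna_pos, 2:8)
  expect_equal(sum(seed_pairs$kind == "GU"), 1L)
  expect_equal(seed_pairs$kind[seed_pairs$mirna_pos == 2], "GU")
})

test_that("duplex_mfe obeys the energy-model contracts", {
  expect_equal(duplex_mfe("AAAA", "AAAA"), 0)
  # an additional stacked WC pair can only stabilize
  set.seed(6)
  for (rep in 1:10) {
    s <- rand_rna(sample(4:8, 1))
    e_short <- duplex_mfe(s, cernaxis:::rna_revcomp(s))
    ext <- paste0(s, "G")
    e_long <- duplex_mfe(ext, cernaxis:::rna_revcomp(ext))
    expect_lte(e_long, e_short)
  }
  # symmetry in the strand roles
  for (rep in 1:20) {
    a <- rand_rna(sample(3:9, 1))
    b <- rand_rna(sample(3:9, 1))
    expect_equal(duplex_mfe(a, b), duplex_mfe(b, a), tolerance = 1e-12)
  }
})

test_that("duplex_mfe and align_score match enumeration oracles on short pairs", {
  set.seed(16)
  for (rep in 1:40) {
    a <- rand_rna(sample(3:8, 1))
    b <- rand_rna(sample(3:8, 1))
    expect_equal(duplex_mfe(a, b), oracle_duplex(a, b), tolerance = 1e-9)
    expect_equal(align_score(a, b, trim_mirna_length = FALSE)$score,
                 oracle_align(a, b), tolerance = 1e-9)
  }
})

test_that("seed_matches finds the heptamer complement with wobble accounting", {
  hits <- seed_matches(mir24, wild_fragment)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 12L)
  expect_equal(hits$n_gu, 1L)
  expect_equal(nrow(seed_matches(mir24, mut_fragment)), 0L)
})

test_that("scan_targets detects the wild-type site and rejects the mutant", {
  sites <- scan_targets(mir24, wild_fragment)
  expect_gte(nrow(sites), 1L)
  expect_equal(sites$seed_class, "7mer-1GU")
  expect_equal(nrow(scan_targets(mir24, mut_fragment)), 0L)
})

test_that("a full-complement site passes all gates and dies by seed mutation", {
  set.seed(26)
  m <- paste(sample(c(rep("G", 6), rep("C", 6), rep("A", 5), rep("U", 5))),
             collapse = "")
  site <- cernaxis:::rna_revcomp(m)
  target <- paste0(rand_rna(30), "GCGCGCGC", site, "GCGCGCGC", rand_rna(30))
  sites <- scan_targets(m, target)
  expect_true(any(sites$passes))
  best <- sites[which.max(sites$align_score), ]
  expect_lte(best$hybrid_mfe, -30)
  expect_lte(best$align_mfe, -45)
  expect_gte(best$align_score, calibrated_score_gate())

  # mutate every seed-pairing base (positions pairing miRNA 2-8)
  hit <- seed_matches(m, target)$start[1]
  seed7 <- substr(target, hit, hit + 6)
  flip <- chartr("ACGU", "CAUG", seed7) # destroys all pairing
  mutated <- paste0(substr(target, 1, hit - 1), flip,
                    substr(target, hit + 7, nchar(target)))
  expect_equal(nrow(scan_targets(m, mutated)), 0L)
})

test_that("candidate-site rate on shuffled sequence matches the analytic seed model", {
  set.seed(36)
  m <- rand_rna(22)
  seed <- substr(m, 2, 8)
  bases <- strsplit(seed, "")[[1]]
  # per-position probability that a uniform base pairs (WC, or wobble for G/U)
  p_pos <- vapply(bases, function(b) if (b %in% c("G", "U")) 0.5 else 0.25,
                  numeric(1))
  p_permissive <- prod(p_pos)
  n_trials <- 400
  L <- 60
  hits <- vapply(seq_len(n_trials), function(i) {
    nrow(seed_matches(m, rand_rna(L), max_gu = 7L)) > 0
  }, logical(1))
  p_window <- 1 - (1 - p_permissive)^(L - 6)
  expect_lt(abs(mean(hits) - p_window),
            4 * sqrt(p_window * (1 - p_window) / n_trials) + 0.01)
})

test_that("alignment_energy scores the pair chain under the duplex model", {
  set.seed(46)
  m <- rand_rna(22)
  res <- align_score(m, cernaxis:::rna_revcomp(m))
  e <- alignment_energy(res$pairs, m, cernaxis:::rna_revcomp(m))
  expect_lt(e, -30)
  expect_gte(e, duplex_mfe(m, cernaxis:::rna_revcomp(m)) - 1e-9)
  expect_equal(alignment_energy(res$pairs[0, ], m, m), 0)
})

test_that("pair_sign encodes the repression pattern", {
  expect_equal(pair_sign("Down", "Up"), "negative")
  expect_equal(pair_sign("Up", "Up"), "positive")
  expect_equal(pair_sign("Down", "Down"), "positive")
  expect_equal(pair_sign(c("Up", "Down"), c("Down", "Down")),
               c("negative", "positive"))
  expect_error(pair_sign("none", "Up"), "direction")
})
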