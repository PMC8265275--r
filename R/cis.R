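# lncRNA cis-target assignment: a lncRNA is a cis candidate for a coding
# gene when it lies within 10 kb upstream or 20 kb downstream of the mRNA
# (boundaries inclusive; upstream/downstream defined relative to the mRNA's
# strand), or intersects it (overlap / anti-overlap by strand equality).
# Candidate pairs must additionally pass a dual co-expression gate
# (Pearson >= 0.6 AND Spearman >= 0.6 across all samples, groups pooled).
# Out-of-window pairs can still qualify as trans candidates through a
# windowed duplex minimum-free-energy rule (< -30 kcal/mol).

#' Classify the positional relation between a lncRNA and an mRNA
#'
#' Vectorized over rows. Intersecting spans give `overlap` (same strand) or
#' `anti-overlap` (opposite strand) at distance 0. Otherwise the gap is the
#' nearest-boundary separation in nt; the lncRNA is `upstream` when it lies
#' 5' of the mRNA with respect to the mRNA's strand and within `up_window`,
#' `downstream` when 3' and within `down_window`, `none` otherwise (the gap
#' is still reported). Pairs on different chromosomes are `none` with
#' distance `NA`.
#'
#' @param lnc,mrna Transcript tibbles (or single rows) with `chrom`,
#'   `strand`, `start`, `end`; recycled to a common length.
#' @param up_window,down_window Window sizes in nt (defaults 10,000 and
#'   20,000, boundaries inclusive).
#' @return Tibble with columns `relation` and `distance`.
#' @export
classify_relation <- function(lnc, mrna, up_window = 10000, down_window = 20000) {
  lnc <- tibble::as_tibble(lnc)
  mrna <- tibble::as_tibble(mrna)
  n <- max(nrow(lnc), nrow(mrna))
  if (nrow(lnc) == 1L) lnc <- lnc[rep(1L, n), ]
  if (nrow(mrna) == 1L) mrna <- mrna[rep(1L, n), ]
  stopifnot(nrow(lnc) == nrow(mrna))
  if (any(!c(lnc$strand, mrna$strand) %in% c("+", "-"))) {
    cx_abort("strand must be '+' or '-'")
  }
  same_chrom <- lnc$chrom == mrna$chrom
  intersects <- same_chrom & lnc$start <= mrna$end & mrna$start <= lnc$end
  lnc_left <- lnc$end < mrna$start
  gap <- ifelse(lnc_left, mrna$start - lnc$end, lnc$start - mrna$end)
  # side of the mRNA the lncRNA sits on, in the mRNA's 5'->3' frame
  is_upstream_side <- ifelse(mrna$strand == "+", lnc_left, !lnc_left)
  relation <- dplyr::case_when(
    !same_chrom ~ "none",
    intersects & lnc$strand == mrna$strand ~ "overlap",
    intersects ~ "anti-overlap",
    is_upstream_side & gap <= up_window ~ "upstream",
    !is_upstream_side & gap <= down_window ~ "downstream",
    TRUE ~ "none"
  )
  distance <- dplyr::case_when(
    !same_chrom ~ NA_real_,
    intersects ~ 0,
    TRUE ~ as.numeric(gap)
  )
  tibble::tibble(relation = relation, distance = distance)
}

#' Pearson and Spearman correlation of two expression vectors
#'
#' Standard product-moment and rank correlations (ties receive average
#' ranks). Constant vectors have no defined correlation and raise an error.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return Tibble with columns `pearson` and `spearman`.
#' @export
expression_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    cx_abort("expression vectors must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    cx_abort("correlation undefined for a constant expression vector")
  }
  tibble::tibble(
    pearson = stats::cor(x, y, method = "pearson"),
    spearman = stats::cor(x, y, method = "spearman")
  )
}

#' @importFrom stats sd
NULL

#' Windowed duplex-MFE trans-candidate rule
#'
#' Slides windows over both sequences and takes the minimum intermolecular
#' duplex free energy over all window pairs; a pair is a trans candidate
#' when that minimum is below `mfe_threshold` (-30 kcal/mol by default).
#'
#' @param lnc_seq,mrna_seq RNA sequences (T accepted as U), each at least
#'   `window` nt long.
#' @param window,step Window length and stride in nt.
#' @param mfe_threshold Threshold in kcal/mol.
#' @return Tibble with `min_mfe` (kcal/mol) and `is_trans`.
#' @export
trans_candidate <- function(lnc_seq, mrna_seq, window = 40L, step = 20L,
                            mfe_threshold = -30) {
  s1 <- as_rna(lnc_seq)
  s2 <- as_rna(mrna_seq)
  check_nucleotides(s1, alphabet = c("A", "C", "G", "U"), what = "lnc_seq")
  check_nucleotides(s2, alphabet = c("A", "C", "G", "U"), what = "mrna_seq")
  if (nchar(s1) < window || nchar(s2) < window) {
    cx_abort(sprintf("both sequences must be at least %d nt for the windowed scan", window))
  }
  mfe <- duplex_windowed_min_cpp(encode_rna(s1), encode_rna(s2),
                                 as.integer(window), as.integer(step))
  tibble::tibble(min_mfe = mfe, is_trans = mfe < mfe_threshold)
}

#' Build cis lncRNA-mRNA candidate pairs
#'
#' Crosses each differentially expressed lncRNA with every mRNA on the same
#' chromosome, applies the window/overlap relation rule and the dual
#' correlation gate, and flags pairs whose mRNA is itself differentially
#' expressed (the network-building intersection).
#'
#' @param annotation Transcript tibble covering lncRNAs and mRNAs.
#' @param expression Expression tibble (FPKM recommended) covering all
#'   transcripts, used for the correlation gate across all samples.
#' @param de_lnc,de_mrna DE result tibbles ([diff_expression()]) for the
#'   lncRNA and mRNA populations.
#' @param up_window,down_window Window rule parameters in nt.
#' @param corr_threshold Dual correlation gate (applied to both Pearson and
#'   Spearman; default 0.6).
#' @return Tibble of passing pairs: `lnc_id`, `mrna_id`, `relation`,
#'   `distance`, `pearson`, `spearman`, `mrna_is_de`.
#' @export
build_cis_pairs <- function(annotation, expression, de_lnc, de_mrna,
                            up_window = 10000, down_window = 20000,
                            corr_threshold = 0.6) {
  annotation <- tibble::as_tibble(annotation)
  lnc_ids <- de_lnc$feature_id[de_lnc$significant]
  lnc_ann <- annotation[annotation$transcript_id %in% lnc_ids, ]
  mrna_ann <- annotation[annotation$biotype == "mRNA", ]
  if (!nrow(lnc_ann) || !nrow(mrna_ann)) {
    return(empty_cis_pairs())
  }
  missing <- setdiff(c(lnc_ann$transcript_id, mrna_ann$transcript_id),
                     expression$feature_id)
  if (length(missing)) {
    cx_abort(sprintf("expression table is missing transcript(s): %s",
                     paste(head(missing, 5), collapse = ", ")))
  }
  pairs <- tidyr::crossing(lnc_id = lnc_ann$transcript_id,
                           mrna_id = mrna_ann$transcript_id)
  li <- match(pairs$lnc_id, lnc_ann$transcript_id)
  mi <- match(pairs$mrna_id, mrna_ann$transcript_id)
  keep <- lnc_ann$chrom[li] == mrna_ann$chrom[mi]
  pairs <- pairs[keep, ]
  li <- li[keep]
  mi <- mi[keep]
  if (!nrow(pairs)) return(empty_cis_pairs())
  rel <- classify_relation(lnc_ann[li, ], mrna_ann[mi, ],
                           up_window = up_window, down_window = down_window)
  pairs <- dplyr::bind_cols(pairs, rel)
  pairs <- pairs[pairs$relation != "none", ]
  if (!nrow(pairs)) return(empty_cis_pairs())
  em <- expr_matrix(expression)
  corr <- purrr::map2(pairs$lnc_id, pairs$mrna_id, function(a, b) {
    x <- em[a, ]
    y <- em[b, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      tibble::tibble(pearson = NA_real_, spearman = NA_real_)
    } else {
      expression_correlation(x, y)
    }
  }) |> purrr::list_rbind()
  pairs <- dplyr::bind_cols(pairs, corr)
  pairs$passes_correlation <- !is.na(pairs$pearson) &
    pairs$pearson >= corr_threshold & pairs$spearman >= corr_threshold
  pairs <- pairs[pairs$passes_correlation, ]
  de_set <- de_mrna$feature_id[de_mrna$significant]
  pairs$mrna_is_de <- pairs$mrna_id %in% de_set
  dplyr::select(pairs, "lnc_id", "mrna_id", "relation", "distance",
                "pearson", "spearman", "mrna_is_de")
}

#' @noRd
empty_cis_pairs <- function() {
  tibble::tibble(lnc_id = character(), mrna_id = character(),
                 relation = character(), distance = numeric(),
                 pearson = numeric(), spearman = numeric(),
                 mrna_is_de = logical())
}
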