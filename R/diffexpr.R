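# Count-based differential expression between two groups (L vs H).
#
# The test statistic follows the pooled-library two-proportion model used by
# early count-based DE tools for library-vs-library comparisons: replicate
# counts are pooled within group and the pooled count for one feature is
# compared with a binomial proportion z-test against the null proportion
# implied by the two library totals. Group means for the fold change, by
# contrast, are computed from per-sample normalized values averaged over
# replicates. Significance uses the joint gate |FC| >= 2 and Q <= 0.001
# (both inclusive), with Q from Benjamini-Hochberg adjustment.

#' Library-size (counts-per-million) normalization
#'
#' @param counts Count tibble (`feature_id` + sample columns), unit `count`.
#' @param design Two-group design tibble.
#' @return List with `expr` (CPM tibble, unit attribute `"CPM"`) and
#'   `factors` (named per-sample scale factors such that
#'   `normalized = count * factor`).
#' @export
normalize_cpm <- function(counts, design) {
  design <- validate_design(design)
  m <- expr_matrix(counts)
  m <- m[, design$sample_id, drop = FALSE]
  totals <- colSums(m)
  if (any(totals == 0)) {
    cx_abort(sprintf("sample '%s' has zero total counts", names(totals)[totals == 0][1]))
  }
  factors <- 1e6 / totals
  norm <- sweep(m, 2, factors, `*`)
  expr <- tibble::tibble(feature_id = counts$feature_id)
  expr <- dplyr::bind_cols(expr, tibble::as_tibble(norm))
  attr(expr, "unit") <- "CPM"
  list(expr = expr, factors = factors)
}

#' Log2 fold change of group means with a between-library scale constant
#'
#' Computes `log2(scale * mean_H / mean_L)`. The scale constant absorbs any
#' residual between-library normalization applied upstream of the reported
#' group means (see [fit_scale_constant()]); `scale = 1` is the plain ratio.
#'
#' @param mean_L,mean_H Positive group mean expression values (vectorized).
#' @param scale Positive scale constant multiplying the raw H/L ratio.
#' @return Numeric vector of log2 fold changes (H over L).
#' @export
log2_fold_change <- function(mean_L, mean_H, scale = 1) {
  if (any(scale <= 0)) cx_abort("scale constant must be positive")
  if (any(mean_L <= 0) || any(mean_H <= 0)) {
    cx_abort("group means must be positive (pseudocount handling is the caller's decision)")
  }
  log2(scale * mean_H / mean_L)
}

#' Fit the between-library scale constant from reference rows
#'
#' Given reference features with printed group means and printed log2 fold
#' changes, each row implies a constant `c_i = 2^log2fc / (mean_H / mean_L)`;
#' the fitted constant is the median of the per-row values. This recovers an
#' undocumented between-library scaling from a published table so that
#' held-out rows can be reproduced.
#'
#' @param rows Tibble with columns `mean_L`, `mean_H`, `log2fc`.
#' @return The fitted scale constant (positive scalar).
#' @export
fit_scale_constant <- function(rows) {
  rows <- tibble::as_tibble(rows)
  stopifnot(all(c("mean_L", "mean_H", "log2fc") %in% names(rows)))
  if (!nrow(rows)) cx_abort("at least one reference row is required")
  if (any(rows$mean_L <= 0) || any(rows$mean_H <= 0)) cx_abort("reference means must be positive")
  stats::median(2^rows$log2fc / (rows$mean_H / rows$mean_L))
}

#' Pooled binomial proportion z-test for one or more features
#'
#' Replicate counts are pooled within group; for each feature the pooled
#' count `k_H` out of `n = k_H + k_L` trials is tested against the null
#' proportion `p0 = N_H / (N_H + N_L)` given by the group library totals,
#' with a two-sided normal tail. Features with `n = 0` get `p = 1`.
#'
#' @param k_L,k_H Pooled per-feature counts in each group (vectorized).
#' @param N_L,N_H Group library totals (scalars).
#' @return Two-sided p-values.
#' @export
de_test <- function(k_L, k_H, N_L, N_H) {
  if (any(c(k_L, k_H) < 0)) cx_abort("counts must be non-negative")
  if (N_L <= 0 || N_H <= 0) cx_abort("library totals must be positive")
  n <- k_L + k_H
  p0 <- N_H / (N_H + N_L)
  phat <- ifelse(n > 0, k_H / n, p0)
  z <- ifelse(n > 0, (phat - p0) / sqrt(p0 * (1 - p0) / pmax(n, 1)), 0)
  2 * stats::pnorm(-abs(z))
}

#' Benjamini-Hochberg adjusted Q-values
#'
#' Step-up adjustment, order-preserving with the input vector.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1)) cx_abort("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Annotate significance and direction on a DE table
#'
#' Significant iff `|log2fc| >= log2(fc_threshold)` and `q <= q_threshold`
#' (both inclusive, matching the conventional |FC| >= 2 / Q <= 0.001 gate);
#' direction is `Up`/`Down` for significant features by the sign of the fold
#' change, `none` otherwise.
#'
#' @param results Tibble with columns `log2fc` and `q`.
#' @param fc_threshold Fold-change gate on the natural scale (default 2).
#' @param q_threshold Q-value gate (default 0.001).
#' @return `results` with `significant` and `direction` columns replaced.
#' @export
call_de <- function(results, fc_threshold = 2, q_threshold = 0.001) {
  results <- tibble::as_tibble(results)
  results |>
    dplyr::mutate(
      significant = abs(.data$log2fc) >= log2(fc_threshold) & .data$q <= q_threshold,
      direction = dplyr::case_when(
        .data$significant & .data$log2fc > 0 ~ "Up",
        .data$significant & .data$log2fc < 0 ~ "Down",
        TRUE ~ "none"
      )
    )
}

#' Two-group differential expression from a count table
#'
#' Runs the full per-feature analysis: CPM normalization for group means,
#' pooled binomial z-test on raw counts, BH adjustment, fold-change gate.
#' A pseudo-expression of `pseudo` normalized units is added to both group
#' means before the log2 ratio (never before testing), so features with zero
#' counts in one group remain reportable.
#'
#' @param counts Count tibble (`feature_id` + sample columns).
#' @param design Two-group design tibble; group labels sorted so the
#'   lexicographically smaller one is `L` unless levels `L`/`H` are used.
#' @param fc_threshold,q_threshold Significance gates (see [call_de()]).
#' @param pseudo Pseudo-expression (CPM units) added before the ratio.
#' @param by_gene Optional named vector mapping feature ids to gene ids;
#'   when supplied, transcript counts are summed per gene before testing.
#' @return A `cx_de` tibble: `feature_id`, `mean_L`, `mean_H`, `log2fc`,
#'   `p`, `q`, `direction`, `significant`.
#' @export
diff_expression <- function(counts, design, fc_threshold = 2, q_threshold = 0.001,
                            pseudo = 0.1, by_gene = NULL) {
  design <- validate_design(design)
  groups <- sort(unique(design$group))
  if (setequal(groups, c("L", "H"))) groups <- c("L", "H")
  if (!is.null(by_gene)) {
    gene <- unname(by_gene[counts$feature_id])
    if (anyNA(gene)) cx_abort("by_gene does not cover all features")
    counts <- counts |>
      dplyr::mutate(feature_id = gene) |>
      dplyr::group_by(.data$feature_id) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), sum), .groups = "drop")
  }
  m <- expr_matrix(counts)[, design$sample_id, drop = FALSE]
  if (any(m < 0)) cx_abort("counts must be non-negative")
  in_L <- design$sample_id[design$group == groups[1]]
  in_H <- design$sample_id[design$group == groups[2]]
  norm <- normalize_cpm(counts, design)
  nm <- expr_matrix(norm$expr)
  mean_L <- rowMeans(nm[, in_L, drop = FALSE])
  mean_H <- rowMeans(nm[, in_H, drop = FALSE])
  k_L <- rowSums(m[, in_L, drop = FALSE])
  k_H <- rowSums(m[, in_H, drop = FALSE])
  p <- de_test(k_L, k_H, N_L = sum(k_L), N_H = sum(k_H))
  res <- tibble::tibble(
    feature_id = counts$feature_id,
    mean_L = mean_L,
    mean_H = mean_H,
    log2fc = log2_fold_change(mean_L + pseudo, mean_H + pseudo),
    p = p,
    q = bh_adjust(p)
  ) |>
    call_de(fc_threshold = fc_threshold, q_threshold = q_threshold)
  structure(res,
            class = c("cx_de", class(res)),
            fc_threshold = fc_threshold, q_threshold = q_threshold,
            groups = stats::setNames(groups, c("L", "H")))
}

#' @method tidy cx_de
#' @export
tidy.cx_de <- function(x, ...) {
  tibble::as_tibble(unclass_de(x))
}

#' @method glance cx_de
#' @export
glance.cx_de <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$direction == "Up"),
    n_down = sum(x$direction == "Down"),
    fc_threshold = attr(x, "fc_threshold"),
    q_threshold = attr(x, "q_threshold")
  )
}

#' Volcano plot of a DE result
#'
#' @param object A `cx_de` result from [diff_expression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cx_de
#' @export
autoplot.cx_de <- function(object, ...) {
  dat <- tidy(object)
  dat$neglog_q <- -log10(pmax(dat$q, 1e-300))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2fc, y = .data$neglog_q,
                                    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(Up = "firebrick", Down = "steelblue",
                                            none = "grey60")) +
    ggplot2::labs(x = "log2 fold change (H/L)", y = "-log10 Q") +
    ggplot2::theme_minimal()
}

#' @noRd
unclass_de <- function(x) {
  class(x) <- setdiff(class(x), "cx_de")
  x
}

#' FPKM from counts and feature lengths
#'
#' `FPKM = count * 1e9 / (length * library_size)`.
#'
#' @param counts Count tibble (`feature_id` + sample columns).
#' @param lengths Named vector of feature lengths in nt.
#' @return FPKM tibble with unit attribute `"FPKM"`.
#' @export
fpkm <- function(counts, lengths) {
  len <- unname(lengths[counts$feature_id])
  if (anyNA(len)) cx_abort("lengths do not cover all features")
  m <- expr_matrix(counts)
  totals <- colSums(m)
  if (any(totals == 0)) cx_abort("zero-total sample column")
  vals <- sweep(m / len, 2, 1e9 / totals, `*`)
  out <- dplyr::bind_cols(tibble::tibble(feature_id = counts$feature_id),
                          tibble::as_tibble(vals))
  attr(out, "unit") <- "FPKM"
  out
}

#' Per-sample FPKM abundance bins
#'
#' Counts features in the three conventional abundance classes
#' `FPKM <= 1`, `1 < FPKM < 10` and `FPKM >= 10` for each sample.
#'
#' @param expr FPKM tibble (unit attribute must be `"FPKM"`).
#' @return Tibble with columns `sample_id`, `low`, `mid`, `high` summing to
#'   the feature count.
#' @export
fpkm_bins <- function(expr) {
  if (!identical(expr_unit(expr), "FPKM")) {
    cx_abort(sprintf("fpkm_bins needs FPKM input, got unit '%s'", expr_unit(expr)))
  }
  m <- expr_matrix(expr)
  tibble::tibble(
    sample_id = colnames(m),
    low = colSums(m <= 1),
    mid = colSums(m > 1 & m < 10),
    high = colSums(m >= 10)
  )
}
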