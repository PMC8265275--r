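# Bundled reference tables: the top-abundant differentially expressed
# lncRNAs, mRNAs and miRNAs of a published chicken liver adipogenesis
# transcriptome study (high- vs low-abdominal-fat broilers, 6 vs 6), with
# their printed group mean expression and log2 fold changes. The printed
# means and fold changes embed an undocumented between-library scale
# constant; fitting it on all-but-one row and reproducing the held-out row
# exercises the fold-change arithmetic end to end.

#' Bundled reference fold-change tables
#'
#' @param table Which table to load: the top-10 abundant differentially
#'   expressed lncRNAs or mRNAs, or the top-20 miRNAs.
#' @return Tibble with columns `feature_id`, `mean_L`, `mean_H`, `log2fc`.
#' @export
fc_reference <- function(table = c("lncRNA", "mRNA", "miRNA")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("ref_", table, ".tsv"),
                      package = "cernaxis", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Reproduce a reference row's log2 fold change by held-out calibration
#'
#' Fits the between-library scale constant ([fit_scale_constant()]) on all
#' rows except the target, then recomputes the target's log2 fold change
#' from its printed group means ([log2_fold_change()]).
#'
#' @param ref Reference tibble (see [fc_reference()]).
#' @param feature_id Row to hold out and reproduce.
#' @return Named list with `scale`, `log2fc` (recomputed) and `printed`.
#' @export
reproduce_reference_log2fc <- function(ref, feature_id) {
  idx <- match(feature_id, ref$feature_id)
  if (is.na(idx)) cx_abort(sprintf("feature '%s' not in reference table", feature_id))
  scale <- fit_scale_constant(ref[-idx, ])
  list(
    scale = scale,
    log2fc = log2_fold_change(ref$mean_L[idx], ref$mean_H[idx], scale = scale),
    printed = ref$log2fc[idx]
  )
}
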