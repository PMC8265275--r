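# Expression matrix IO. An expression table is a tibble with a `feature_id`
# column followed by one numeric column per sample; the measurement unit
# ("count" or "FPKM") travels as the "unit" attribute.

#' Read an expression table from a TSV file
#'
#' The header row names the samples. All samples listed in `design` must be
#' present; columns not listed in the design are dropped with a warning.
#'
#' @param path Path to a TSV file whose first column holds feature ids.
#' @param design A two-group design tibble (`sample_id`, `group`); see
#'   [validate_design()].
#' @param unit Measurement unit of the values, `"count"` or `"FPKM"`.
#' @return A tibble `feature_id` + one column per design sample, in design
#'   order, with attribute `unit`.
#' @export
read_expression <- function(path, design, unit = c("count", "FPKM")) {
  unit <- match.arg(unit)
  design <- validate_design(design)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab)[1] <- "feature_id"
  missing <- setdiff(design$sample_id, names(tab))
  if (length(missing)) {
    cx_abort(sprintf("expression table is missing design samples: %s",
                     paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(tab)[-1], design$sample_id)
  if (length(extra)) {
    rlang::warn(sprintf("dropping %d column(s) not in the design: %s",
                        length(extra), paste(extra, collapse = ", ")))
  }
  tab <- dplyr::select(tab, "feature_id", dplyr::all_of(design$sample_id))
  vals <- as.matrix(tab[-1])
  if (!is.numeric(vals)) cx_abort("expression values must be numeric")
  if (anyNA(vals)) cx_abort("expression table contains missing values")
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    cx_abort(sprintf("negative expression value for feature '%s', sample '%s'",
                     tab$feature_id[bad[1]], design$sample_id[bad[2]]))
  }
  if (anyDuplicated(tab$feature_id)) cx_abort("duplicate feature ids in expression table")
  attr(tab, "unit") <- unit
  tab
}

#' Write an expression table to TSV
#'
#' @param expr Expression tibble (`feature_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet (design) from TSV
#'
#' @param path TSV with columns `sample_id` and `group`.
#' @return Validated design tibble.
#' @export
read_design <- function(path) {
  validate_design(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Expression values as a numeric matrix
#'
#' @param expr Expression tibble (`feature_id` + sample columns).
#' @return Numeric matrix with feature ids as rownames.
#' @export
expr_matrix <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$feature_id
  m
}

#' @noRd
expr_unit <- function(expr) attr(expr, "unit") %||% "count"
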