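#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Abort with a cernaxis-classed condition
#' @noRd
cx_abort <- function(msg, class = "cernaxis_error") {
  rlang::abort(msg, class = class)
}

#' Validate a two-group design tibble
#'
#' A design assigns every sample to exactly one of two groups, conventionally
#' `L` (low) and `H` (high). Both groups must be non-empty.
#'
#' @param design A data frame with columns `sample_id` and `group`.
#' @return The design as a tibble, invisibly validated.
#' @export
validate_design <- function(design) {
  design <- tibble::as_tibble(design)
  if (!all(c("sample_id", "group") %in% names(design))) {
    cx_abort("design must have columns 'sample_id' and 'group'")
  }
  if (anyDuplicated(design$sample_id)) {
    cx_abort("design assigns some sample more than once")
  }
  groups <- unique(design$group)
  if (length(groups) != 2L) {
    cx_abort(sprintf("design must define exactly two groups, found %d", length(groups)))
  }
  if (any(table(design$group) == 0L)) cx_abort("both groups must be non-empty")
  design
}

# sequence alphabet helpers ---------------------------------------------------

#' Normalize a nucleotide string to the RNA alphabet (uppercase, T -> U)
#' @noRd
as_rna <- function(x) chartr("T", "U", toupper(x))

#' @noRd
check_nucleotides <- function(x, alphabet = c("A", "C", "G", "U", "T"), what = "sequence") {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    cx_abort(sprintf(
      "invalid character '%s' at position %d of %s",
      chars[bad[1]], bad[1], what
    ))
  }
  invisible(TRUE)
}

#' Reverse complement in the RNA alphabet
#' @noRd
rna_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", as_rna(x)), "")[[1]]), collapse = "")
}

#' Watson-Crick / wobble pairing predicate for single RNA bases
#' @noRd
is_wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

#' @noRd
is_gu_pair <- function(a, b) (a == "G" & b == "U") | (a == "U" & b == "G")
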