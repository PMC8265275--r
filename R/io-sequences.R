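# FASTA sequence IO (Biostrings-backed). Ids are truncated at the first
# whitespace; sequences are uppercased; T -> U conversion on request for
# RNA-context consumers.

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param rna If `TRUE`, convert `T` to `U` so sequences are in the RNA
#'   alphabet expected by the duplex and alignment scorers.
#' @return A named character vector, one element per record. Ids are the FASTA
#'   headers truncated at the first whitespace.
#' @export
read_sequences <- function(path, rna = FALSE) {
  if (!file.exists(path)) cx_abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    cx_abort(sprintf("duplicate FASTA id '%s'", ids[which(duplicated(ids))[1]]))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  iupac <- c(strsplit("ACGTUNRYSWKMBDHV", "")[[1]])
  for (i in seq_along(seqs)) {
    check_nucleotides(seqs[[i]], alphabet = iupac,
                      what = sprintf("sequence '%s'", ids[i]))
  }
  if (rna) seqs <- chartr("T", "U", seqs)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
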