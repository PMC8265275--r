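# Transcript biotype classification by an ensemble vote over four
# coding-potential criteria, plus the small-RNA annotation priority rule.
#
# The four voters are a CPC-like score (noncoding iff < 0), a
# txCdsPredict-like score (noncoding iff < 500), a CNC-like score (noncoding
# iff < 0) and a Pfam hit (noncoding iff absent). A transcript is called
# lncRNA when at least three of four vote noncoding, mRNA when at least three
# vote coding, and ambiguous on a 2-2 split. Threshold comparisons are
# strict: a score equal to 0 (or 500) is a coding vote.

#' Ensemble biotype vote from four coding-potential scores
#'
#' @param scores Tibble (or data frame) with columns `cpc`, `txcds`, `cnc`
#'   (finite numerics) and `pfam_hit` (logical). One row per transcript;
#'   additional columns (e.g. `transcript_id`) are carried through.
#' @return The input tibble with `noncoding_votes`, `coding_votes` and
#'   `biotype` (`mRNA`, `lncRNA` or `ambiguous`) columns appended.
#' @export
vote_biotype <- function(scores) {
  scores <- tibble::as_tibble(scores)
  stopifnot(all(c("cpc", "txcds", "cnc", "pfam_hit") %in% names(scores)))
  num <- as.matrix(scores[c("cpc", "txcds", "cnc")])
  if (any(!is.finite(num))) cx_abort("coding-potential scores must be finite")
  nc <- (scores$cpc < 0) + (scores$txcds < 500) + (scores$cnc < 0) + (!scores$pfam_hit)
  scores |>
    dplyr::mutate(
      noncoding_votes = as.integer(nc),
      coding_votes = 4L - .data$noncoding_votes,
      biotype = dplyr::case_when(
        .data$noncoding_votes >= 3L ~ "lncRNA",
        .data$coding_votes >= 3L ~ "mRNA",
        TRUE ~ "ambiguous"
      )
    )
}

#' Longest open reading frame on the forward strand
#'
#' Scans all three frames of the presented (already stranded) sequence for
#' the longest ATG...stop open reading frame. The returned length is in
#' nucleotides and includes the stop codon.
#'
#' @param seq Nucleotide string over A/C/G/T (U accepted as T).
#' @return Named numeric vector `c(start, length)`, 1-based; `c(0, 0)` when
#'   no complete ORF exists.
#' @export
longest_orf <- function(seq) {
  seq <- chartr("U", "T", toupper(seq))
  check_nucleotides(seq, alphabet = c("A", "C", "G", "T"))
  n <- nchar(seq)
  best_start <- 0L
  best_len <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts_at <- seq.int(frame + 1L, by = 3L, length.out = max(0L, (n - frame) %/% 3L))
    if (!length(starts_at)) next
    codons <- substring(seq, starts_at, starts_at + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% stops
    stop_idx <- which(is_stop)
    for (s in which(is_start)) {
      nxt <- stop_idx[stop_idx >= s]
      if (!length(nxt)) next
      len <- (nxt[1] - s + 1L) * 3L
      if (len > best_len) {
        best_len <- len
        best_start <- starts_at[s]
      }
    }
  }
  c(start = best_start, length = best_len)
}

# Fickett (1982) TESTCODE lookup tables: position-asymmetry and composition
# probabilities with their weights, as tabulated in the original publication
# (the same constants used by CPAT-style reimplementations).
fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
fickett_position_par <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
fickett_content_par <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)

#' Fickett TESTCODE score of a nucleotide sequence
#'
#' Combines per-base position-asymmetry values (max/min codon-phase usage)
#' and composition fractions through the published probability tables. Coding
#' sequences typically score above 0.95, non-coding below 0.74.
#'
#' @param seq Nucleotide string (U accepted as T).
#' @return The TESTCODE score (unitless).
#' @export
fickett_score <- function(seq) {
  seq <- chartr("U", "T", toupper(seq))
  check_nucleotides(seq, alphabet = c("A", "C", "G", "T"))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  phase <- (seq_along(chars) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    counts <- vapply(0:2, function(p) sum(chars[phase == p] == b), numeric(1))
    pos_val <- max(counts) / (min(counts) + 1)
    idx <- which(pos_val >= fickett_position_par)[1]
    score <- score + fickett_position_prob[[b]][idx] * fickett_position_weight[[b]]
    cont_val <- mean(chars == b)
    idx <- which(cont_val >= fickett_content_par)[1]
    score <- score + fickett_content_prob[[b]][idx] * fickett_content_weight[[b]]
  }
  score
}

#' Built-in coding-potential scores for a transcript sequence
#'
#' A self-contained scorer producing the same score layout as the external
#' CPC / txCdsPredict / CNC / Pfam ensemble, shifted so the conventional
#' decision thresholds (0, 500, 0) keep their meaning: the txCdsPredict-like
#' score is the longest ORF length in nt; the CPC-like score is the ORF
#' coverage fraction minus 0.3; the CNC-like score is the Fickett TESTCODE
#' score minus 0.95. No Pfam search is performed, so `pfam_hit` is always
#' `FALSE`; a built-in mRNA call therefore requires all three numeric scores
#' to vote coding.
#'
#' @param seq Nucleotide string of length >= 200 (the lncRNA definition floor).
#' @return Tibble with columns `cpc`, `txcds`, `cnc`, `pfam_hit`.
#' @export
builtin_coding_scores <- function(seq) {
  if (nchar(seq) < 200L) {
    cx_abort(sprintf("sequence must be >= 200 nt for coding-potential scoring (got %d)",
                     nchar(seq)))
  }
  orf <- longest_orf(seq)
  tibble::tibble(
    cpc = unname(orf["length"]) / nchar(seq) - 0.3,
    txcds = unname(orf["length"]),
    cnc = fickett_score(seq) - 0.95,
    pfam_hit = FALSE
  )
}

#' Classify transcripts of unknown biotype
#'
#' Resolves `unknown` biotypes in a transcript table, preferring an external
#' score table (CPC/txCdsPredict/CNC/Pfam columns, thresholds applied
#' verbatim) and falling back to the built-in scorer on the transcript
#' sequences. Transcripts whose vote splits 2-2 are labelled `ambiguous` and
#' take part in neither the lncRNA nor the mRNA downstream sets.
#'
#' @param transcripts Transcript tibble (see [read_annotation()]).
#' @param seqs Named character vector of transcript sequences (for the
#'   built-in scorer).
#' @param scores Optional external score tibble with columns `transcript_id`,
#'   `cpc`, `txcds`, `cnc`, `pfam_hit`.
#' @return `transcripts` with `unknown` biotypes replaced by the vote call.
#' @export
classify_transcripts <- function(transcripts, seqs = NULL, scores = NULL) {
  transcripts <- tibble::as_tibble(transcripts)
  todo <- which(transcripts$biotype == "unknown")
  if (!length(todo)) return(transcripts)
  ids <- transcripts$transcript_id[todo]
  if (!is.null(scores)) {
    scores <- tibble::as_tibble(scores)
    scores <- scores[match(ids, scores$transcript_id), , drop = FALSE]
    if (anyNA(scores$transcript_id)) {
      cx_abort("external score table does not cover all unknown transcripts")
    }
    score_tab <- scores
  } else {
    if (is.null(seqs)) cx_abort("either `seqs` or `scores` is required to classify")
    missing <- setdiff(ids, names(seqs))
    if (length(missing)) {
      cx_abort(sprintf("no sequence for transcript(s): %s",
                       paste(head(missing, 5), collapse = ", ")))
    }
    score_tab <- purrr::map_dfr(seqs[ids], builtin_coding_scores)
    score_tab$transcript_id <- ids
  }
  call <- vote_biotype(score_tab)
  transcripts$biotype[todo] <- call$biotype
  transcripts
}

#' Annotate a small RNA by database priority
#'
#' When a small RNA matches several reference databases, the annotation with
#' the highest priority wins: miRBase > piRNAbank > snoRNA > Rfam.
#'
#' @param hits Character vector (possibly empty) of database labels among
#'   `"miRBase"`, `"piRNAbank"`, `"snoRNA"`, `"Rfam"` (case-insensitive).
#' @return The winning label, or `"unannotated"` for an empty hit set.
#' @export
annotate_small_rna <- function(hits) {
  priority <- c("miRBase", "piRNAbank", "snoRNA", "Rfam")
  if (!length(hits)) return("unannotated")
  idx <- match(tolower(hits), tolower(priority))
  if (anyNA(idx)) {
    cx_abort(sprintf("unknown small RNA database label '%s'", hits[which(is.na(idx))[1]]))
  }
  priority[min(idx)]
}
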