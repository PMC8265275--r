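# GTF-backed transcript annotation. Coordinates are 1-based inclusive
# throughout (GTF convention); exon lines are merged to transcript spans.

#' Read transcript annotation from a GTF file
#'
#' Parses a GTF file into one row per transcript. Exon lines belonging to the
#' same `transcript_id` are merged to the enclosing span (min start, max end).
#' Biotype is taken from a `transcript_biotype`, `gene_biotype` or `biotype`
#' attribute when present and mapped onto `mRNA` / `lncRNA`; transcripts
#' without a recognisable biotype are labelled `unknown` and left for the
#' coding-potential classifier to resolve.
#'
#' @param path Path to a tab-delimited GTF file.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `biotype`, `novel`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) cx_abort(sprintf("annotation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  body_idx <- which(keep)
  if (!length(body_idx)) {
    return(tibble::tibble(
      transcript_id = character(), gene_id = character(), chrom = character(),
      strand = character(), start = integer(), end = integer(),
      biotype = character(), novel = logical()
    ))
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 9L)
  if (length(bad)) {
    cx_abort(sprintf("malformed GTF line %d: expected 9 tab-delimited fields, found %d",
                     body_idx[bad[1]], n_fields[bad[1]]))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    cx_abort(sprintf("malformed GTF line %d: non-numeric coordinates", body_idx[bad]))
  }
  strand <- vapply(fields, `[[`, "", 7L)
  if (any(!strand %in% c("+", "-"))) {
    bad <- which(!strand %in% c("+", "-"))[1]
    cx_abort(sprintf("malformed GTF line %d: strand must be '+' or '-'", body_idx[bad]))
  }
  attrs <- vapply(fields, `[[`, "", 9L)
  get_attr <- function(key) {
    m <- stringr::str_match(attrs, paste0(key, ' "([^"]*)"'))[, 2]
    m
  }
  tid <- get_attr("transcript_id")
  if (anyNA(tid)) {
    cx_abort(sprintf("malformed GTF line %d: missing transcript_id attribute",
                     body_idx[which(is.na(tid))[1]]))
  }
  biotype_raw <- dplyr::coalesce(get_attr("transcript_biotype"),
                                 get_attr("gene_biotype"),
                                 get_attr("biotype"))
  out <- tibble::tibble(
    transcript_id = tid,
    gene_id = dplyr::coalesce(get_attr("gene_id"), tid),
    chrom = vapply(fields, `[[`, "", 1L),
    strand = strand,
    start = start,
    end = end,
    biotype = map_biotype(biotype_raw),
    novel = dplyr::coalesce(tolower(get_attr("novel")), "false") %in% c("true", "1", "yes")
  )
  merged <- out |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      gene_id = dplyr::first(.data$gene_id),
      n_chrom = dplyr::n_distinct(.data$chrom),
      n_strand = dplyr::n_distinct(.data$strand),
      chrom = dplyr::first(.data$chrom),
      strand = dplyr::first(.data$strand),
      start = min(.data$start),
      end = max(.data$end),
      biotype = resolve_biotype(.data$biotype),
      novel = any(.data$novel),
      .groups = "drop"
    )
  conflict <- merged$n_chrom > 1L | merged$n_strand > 1L
  if (any(conflict)) {
    cx_abort(sprintf("transcript_id '%s' has conflicting coordinates (chromosome or strand)",
                     merged$transcript_id[which(conflict)[1]]))
  }
  bad_span <- merged$start < 1L | merged$end < merged$start
  if (any(bad_span)) {
    cx_abort(sprintf("transcript '%s' has an invalid span", merged$transcript_id[which(bad_span)[1]]))
  }
  dplyr::select(merged, -"n_chrom", -"n_strand")
}

#' @noRd
map_biotype <- function(x) {
  dplyr::case_when(
    is.na(x) ~ "unknown",
    grepl("lncRNA|lincRNA|lnc_RNA", x, ignore.case = TRUE) ~ "lncRNA",
    grepl("protein_coding|mRNA", x, ignore.case = TRUE) ~ "mRNA",
    TRUE ~ "unknown"
  )
}

#' @noRd
resolve_biotype <- function(x) {
  known <- setdiff(unique(x), "unknown")
  if (length(known) == 1L) known else "unknown"
}

#' Write transcript annotation to a GTF file
#'
#' One `transcript` feature line is written per record, carrying
#' `transcript_id`, `gene_id`, `transcript_biotype` and `novel` attributes.
#'
#' @param transcripts A transcript tibble as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(transcripts, path) {
  stopifnot(all(c("transcript_id", "gene_id", "chrom", "strand", "start", "end") %in%
                  names(transcripts)))
  transcripts <- dplyr::arrange(tibble::as_tibble(transcripts), .data$transcript_id)
  biotype <- if ("biotype" %in% names(transcripts)) transcripts$biotype else "unknown"
  gtf_bio <- dplyr::case_when(
    biotype == "mRNA" ~ "protein_coding",
    biotype == "lncRNA" ~ "lncRNA",
    TRUE ~ NA_character_
  )
  novel <- if ("novel" %in% names(transcripts)) transcripts$novel else FALSE
  attr_col <- paste0(
    'gene_id "', transcripts$gene_id, '"; ',
    'transcript_id "', transcripts$transcript_id, '"; ',
    ifelse(is.na(gtf_bio), "", paste0('transcript_biotype "', gtf_bio, '"; ')),
    'novel "', tolower(as.character(novel)), '";'
  )
  lines <- paste(transcripts$chrom, "cernaxis", "transcript",
                 transcripts$start, transcripts$end, ".", transcripts$strand, ".",
                 attr_col, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
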