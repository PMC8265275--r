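# miRNA binding-site discovery: seed-anchored candidate detection,
# position-weighted complementarity alignment, and intermolecular duplex
# minimum free energy.
#
# The alignment scoring scheme is a documented re-design of the
# miRanda-style position-weighted local alignment: Watson-Crick pair +5,
# G:U wobble +2, mismatch -3, gap open -9, gap extend -4, with every
# contribution at miRNA positions 2-8 (the seed) multiplied by 4. On that
# scale a perfectly complementary 22-mer scores 215; the conventional
# external score gate of 300 (miRanda scale, perfect 22-mer ~460) is
# therefore linearly calibrated to 300 * 215 / 460 when built-in scores are
# used. External score tables bypass the calibration and use the printed
# thresholds verbatim.

#' @noRd
encode_rna <- function(seq) {
  codes <- c(A = 0L, C = 1L, G = 2L, U = 3L)
  chars <- strsplit(as_rna(seq), "", fixed = TRUE)[[1]]
  out <- codes[chars]
  if (anyNA(out)) {
    cx_abort(sprintf("invalid RNA character '%s' at position %d",
                     chars[which(is.na(out))[1]], which(is.na(out))[1]))
  }
  unname(out)
}

#' Intermolecular duplex minimum free energy
#'
#' Minimum free energy over intermolecular secondary structures of the two
#' strands (no intramolecular pairs, no pseudoknots) under a simplified
#' nearest-neighbor model: stack terms from pair strengths (CG/GC 3.4,
#' AU/UA 1.3, GU/UG 0.9 kcal/mol, stack = minus the mean of the flanking
#' pair strengths), bulges up to 3 nt and internal loops up to 4 nt with
#' size-dependent penalties. Returns 0 when no stabilizing structure exists.
#'
#' @param s1,s2 RNA sequences 5'->3' (T accepted as U).
#' @return MFE in kcal/mol (never positive).
#' @export
duplex_mfe <- function(s1, s2) {
  duplex_mfe_cpp(encode_rna(s1), encode_rna(s2))
}

# alignment scoring constants
ALIGN_WC <- 5
ALIGN_GU <- 2
ALIGN_MISMATCH <- -3
ALIGN_GAP_OPEN <- -9
ALIGN_GAP_EXT <- -4
SEED_WEIGHT <- 4
SEED_RANGE <- 2:8

#' Position-weighted complementarity alignment of a miRNA against a target
#' window
#'
#' Best antiparallel local alignment of the miRNA (5'->3') against the
#' window (5'->3'), scored +5 per Watson-Crick pair, +2 per G:U wobble,
#' -3 per mismatch, -9/-4 affine gaps; contributions at miRNA positions 2-8
#' are multiplied by 4 (gap penalties take the weight of the miRNA position
#' they are charged at). The score is floored at 0.
#'
#' @param mirna miRNA sequence, 18-26 nt.
#' @param window Target window sequence, at least as long as the miRNA.
#' @param trim_mirna_length If `FALSE`, skip the 18-26 nt miRNA length check
#'   (used by internal oracles on short sequences).
#' @return List with `score` (numeric) and `pairs`, a tibble of paired
#'   positions (`mirna_pos`, `target_pos`, `kind` = WC/GU) for the best
#'   alignment (empty when the score is 0).
#' @export
align_score <- function(mirna, window, trim_mirna_length = TRUE) {
  m_seq <- as_rna(mirna)
  w_seq <- as_rna(window)
  check_nucleotides(m_seq, alphabet = c("A", "C", "G", "U"), what = "mirna")
  check_nucleotides(w_seq, alphabet = c("A", "C", "G", "U"), what = "window")
  m <- strsplit(m_seq, "")[[1]]
  if (trim_mirna_length && !(length(m) >= 18L && length(m) <= 26L)) {
    cx_abort(sprintf("miRNA must be 18-26 nt (got %d)", length(m)))
  }
  w <- rev(strsplit(w_seq, "")[[1]]) # reversed window: antiparallel pairing
  nm <- length(m)
  nw <- length(w)
  if (trim_mirna_length && nw < nm) cx_abort("window must be at least miRNA length")
  wgt <- ifelse(seq_len(nm) %in% SEED_RANGE, SEED_WEIGHT, 1)
  NEG <- -1e9
  M <- matrix(NEG, nm + 1, nw + 1)
  X <- matrix(NEG, nm + 1, nw + 1) # gap consuming miRNA bases
  Y <- matrix(NEG, nm + 1, nw + 1) # gap consuming window bases
  for (i in seq_len(nm)) {
    wi <- wgt[i]
    for (k in seq_len(nw)) {
      sub <- if (is_wc_pair(m[i], w[k])) ALIGN_WC
             else if (is_gu_pair(m[i], w[k])) ALIGN_GU
             else ALIGN_MISMATCH
      M[i + 1, k + 1] <- wi * sub +
        max(0, M[i, k], X[i, k], Y[i, k])
      X[i + 1, k + 1] <- max(M[i, k + 1] + wi * ALIGN_GAP_OPEN,
                             X[i, k + 1] + wi * ALIGN_GAP_EXT)
      Y[i + 1, k + 1] <- max(M[i + 1, k] + wi * ALIGN_GAP_OPEN,
                             Y[i + 1, k] + wi * ALIGN_GAP_EXT)
    }
  }
  best <- max(M)
  if (best <= 0) {
    return(list(score = 0,
                pairs = tibble::tibble(mirna_pos = integer(), target_pos = integer(),
                                       kind = character())))
  }
  end <- which(M == best, arr.ind = TRUE)[1, ]
  pairs <- traceback_pairs(M, X, Y, m, w, wgt, end[1] - 1L, end[2] - 1L)
  pairs$target_pos <- nw - pairs$target_pos + 1L # back to window coordinates
  list(score = best, pairs = dplyr::arrange(pairs, .data$mirna_pos))
}

#' @noRd
traceback_pairs <- function(M, X, Y, m, w, wgt, i, k) {
  pairs <- list()
  state <- "M"
  while (i > 0 && k > 0) {
    if (state == "M") {
      if (is_wc_pair(m[i], w[k]) || is_gu_pair(m[i], w[k])) {
        kind <- if (is_wc_pair(m[i], w[k])) "WC" else "GU"
        pairs[[length(pairs) + 1L]] <- c(i, k, kind)
      }
      prev <- c(0, M[i, k], X[i, k], Y[i, k])
      state <- c("stop", "M", "X", "Y")[which.max(prev)]
      i <- i - 1L
      k <- k - 1L
      if (state == "stop") break
    } else if (state == "X") {
      from_open <- M[i, k + 1] + wgt[i] * ALIGN_GAP_OPEN
      state <- if (X[i + 1, k + 1] == from_open) "M" else "X"
      i <- i - 1L
    } else {
      from_open <- M[i + 1, k] + wgt[i] * ALIGN_GAP_OPEN
      state <- if (Y[i + 1, k + 1] == from_open) "M" else "Y"
      k <- k - 1L
    }
  }
  if (!length(pairs)) {
    return(tibble::tibble(mirna_pos = integer(), target_pos = integer(),
                          kind = character()))
  }
  mat <- do.call(rbind, pairs)
  tibble::tibble(mirna_pos = as.integer(mat[, 1]),
                 target_pos = as.integer(mat[, 2]),
                 kind = mat[, 3])
}

#' Energy of an alignment's base-pair chain
#'
#' Sums nearest-neighbor stack terms over contiguous aligned pairs and loop
#' penalties over small interruptions, under the same energy model as
#' [duplex_mfe()]; interruptions larger than the model's loop caps split the
#' chain into independent helices.
#'
#' @param pairs Pair tibble from [align_score()] (`mirna_pos`, `target_pos`).
#' @param mirna,window The aligned sequences (window in original 5'->3'
#'   orientation).
#' @return Energy in kcal/mol (0 for fewer than 2 pairs).
#' @export
alignment_energy <- function(pairs, mirna, window) {
  if (nrow(pairs) < 2L) return(0)
  m <- encode_rna(mirna)
  w <- encode_rna(window)
  ord <- order(pairs$mirna_pos)
  mi <- pairs$mirna_pos[ord]
  wi <- pairs$target_pos[ord] # decreasing in window coords (antiparallel)
  e <- 0
  for (t in seq_len(length(mi) - 1L)) {
    a <- mi[t + 1L] - mi[t] - 1L
    b <- wi[t] - wi[t + 1L] - 1L
    if (a < 0 || b < 0) next
    if (a == 0 && b == 0) {
      e <- e + stack_energy_cpp(m[mi[t]], w[wi[t]], m[mi[t + 1L]], w[wi[t + 1L]])
    } else {
      pen <- loop_penalty_cpp(a, b)
      if (!is.na(pen)) e <- e + pen
    }
  }
  min(e, 0)
}

#' Calibrated internal alignment score gate
#'
#' Maps the conventional external score gate (miRanda scale, where a perfect
#' 22-mer scores about 460) onto the built-in scale (perfect 22-mer = 215).
#'
#' @param external_gate External-scale score gate (default 300).
#' @return Gate on the built-in score scale.
#' @export
calibrated_score_gate <- function(external_gate = 300) {
  external_gate * 215 / 460
}

#' Default miRNA target-site thresholds
#'
#' @param score_gate Alignment score gate; defaults to the calibrated
#'   internal equivalent of the external 300 gate.
#' @param align_mfe_max Alignment-energy gate in kcal/mol (default -45).
#' @param hybrid_mfe_max Duplex-MFE gate in kcal/mol (default -30).
#' @param max_gu Maximum G:U wobbles allowed in the seed (default 1).
#' @return Named list of thresholds.
#' @export
site_thresholds <- function(score_gate = calibrated_score_gate(),
                            align_mfe_max = -45,
                            hybrid_mfe_max = -30,
                            max_gu = 1L) {
  list(score_gate = score_gate, align_mfe_max = align_mfe_max,
       hybrid_mfe_max = hybrid_mfe_max, max_gu = max_gu)
}

#' @noRd
wc_partner <- c(A = "U", U = "A", G = "C", C = "G")

#' Locate seed-complementary heptamers in a target sequence
#'
#' A candidate site pairs all of miRNA positions 2-8 with at most `max_gu`
#' G:U wobbles and no mismatch. Returns 1-based start positions of the
#' 7-mer on the target (5'->3'), with the wobble count of each hit.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param target Target sequence 5'->3'.
#' @param max_gu Maximum seed wobbles.
#' @return Tibble with `start` and `n_gu`.
#' @export
seed_matches <- function(mirna, target, max_gu = 1L) {
  m <- strsplit(as_rna(mirna), "")[[1]]
  t_seq <- as_rna(target)
  # target position k of the site (k = 1..7) pairs miRNA position 9-k
  classes <- vapply(1:7, function(k) {
    b <- m[9 - k]
    allowed <- wc_partner[[b]]
    if (b == "G") allowed <- c(allowed, "U")
    if (b == "U") allowed <- c(allowed, "G")
    paste0("[", paste(allowed, collapse = ""), "]")
  }, character(1))
  pattern <- paste0("(?=", paste(classes, collapse = ""), ")")
  hits <- gregexpr(pattern, t_seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(tibble::tibble(start = integer(), n_gu = integer()))
  t_chars <- strsplit(t_seq, "")[[1]]
  starts <- as.integer(hits)
  n_gu <- vapply(starts, function(q) {
    sum(vapply(1:7, function(k) is_gu_pair(m[9 - k], t_chars[q + k - 1L]), logical(1)))
  }, integer(1))
  out <- tibble::tibble(start = starts, n_gu = n_gu)
  out[out$n_gu <= max_gu, ]
}

#' Scan a target sequence for miRNA binding sites
#'
#' Slides a window (default 30 nt, stride 5, tail window included) over the
#' target; windows containing a seed-complementary heptamer (all of miRNA
#' positions 2-8 paired, at most one G:U, no mismatch) become candidate
#' sites, each scored by the position-weighted alignment and the duplex MFE.
#' A site passes when the alignment score meets the (calibrated) score gate
#' and both energy gates hold. Overlapping candidates are merged keeping the
#' best-scoring representative.
#'
#' @param mirna miRNA sequence 5'->3' (18-26 nt).
#' @param target_seq Target sequence 5'->3' (>= 30 nt).
#' @param thresholds Threshold list from [site_thresholds()].
#' @param mirna_id,target_id Ids copied into the output.
#' @param window,step Window length and stride in nt.
#' @return Tibble of candidate sites: `mirna_id`, `target_id`,
#'   `target_start`, `target_end`, `seed_class`, `align_score`, `align_mfe`,
#'   `hybrid_mfe`, `passes`.
#' @export
scan_targets <- function(mirna, target_seq, thresholds = site_thresholds(),
                         mirna_id = "mirna", target_id = "target",
                         window = 30L, step = 5L) {
  if (is.null(thresholds$score_gate)) cx_abort("threshold config missing score_gate")
  m_seq <- as_rna(mirna)
  t_seq <- as_rna(target_seq)
  n <- nchar(t_seq)
  if (n < window) cx_abort(sprintf("target must be at least %d nt", window))
  starts <- unique(c(seq(1L, n - window + 1L, by = step), n - window + 1L))
  # locate seed hits once on the full target; only stride windows that fully
  # contain a hit heptamer are aligned and energy-scored
  hits_all <- seed_matches(m_seq, t_seq, max_gu = thresholds$max_gu)
  cand <- sort(unique(unlist(lapply(hits_all$start, function(q) {
    starts[starts <= q & starts + window - 1L >= q + 6L]
  }))))
  sites <- list()
  for (ws in cand) {
    win <- substr(t_seq, ws, ws + window - 1L)
    hits <- seed_matches(m_seq, win, max_gu = thresholds$max_gu)
    if (!nrow(hits)) next
    aln <- align_score(m_seq, win)
    a_mfe <- alignment_energy(aln$pairs, m_seq, win)
    h_mfe <- duplex_mfe(m_seq, win)
    span <- if (nrow(aln$pairs)) range(aln$pairs$target_pos) else c(hits$start[1], hits$start[1] + 6L)
    seed_class <- if (min(hits$n_gu) == 0L) "7mer-WC" else "7mer-1GU"
    sites[[length(sites) + 1L]] <- tibble::tibble(
      mirna_id = mirna_id, target_id = target_id,
      target_start = ws + span[1] - 1L, target_end = ws + span[2] - 1L,
      seed_class = seed_class,
      align_score = aln$score, align_mfe = a_mfe, hybrid_mfe = h_mfe,
      passes = aln$score >= thresholds$score_gate &
        a_mfe <= thresholds$align_mfe_max &
        h_mfe <= thresholds$hybrid_mfe_max
    )
  }
  if (!length(sites)) {
    return(tibble::tibble(mirna_id = character(), target_id = character(),
                          target_start = integer(), target_end = integer(),
                          seed_class = character(), align_score = numeric(),
                          align_mfe = numeric(), hybrid_mfe = numeric(),
                          passes = logical()))
  }
  merge_sites(purrr::list_rbind(sites))
}

#' @noRd
merge_sites <- function(sites) {
  sites <- dplyr::arrange(sites, dplyr::desc(.data$align_score), .data$target_start)
  kept <- sites[0, ]
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    overlaps <- nrow(kept) > 0 &&
      any(s$target_start <= kept$target_end & kept$target_start <= s$target_end)
    if (!overlaps) kept <- dplyr::bind_rows(kept, s)
  }
  dplyr::arrange(kept, .data$target_start)
}

#' Sign of a DE miRNA-target pair
#'
#' Negative when the miRNA and its target move in opposite directions
#' between groups (the canonical repressive pattern), positive when they
#' move together.
#'
#' @param dir_mirna,dir_target Direction labels (`Up`/`Down`), vectorized.
#' @return Character vector of `"negative"`/`"positive"`.
#' @export
pair_sign <- function(dir_mirna, dir_target) {
  ok <- c("Up", "Down")
  if (any(!dir_mirna %in% ok) || any(!dir_target %in% ok)) {
    cx_abort("pair_sign requires significant DE directions (Up/Down)")
  }
  ifelse(dir_mirna != dir_target, "negative", "positive")
}
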