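# Seeded synthetic-data generator.
#
# Emulates a 6-vs-6 two-group liver transcriptome design: protein-coding
# genes and lncRNAs placed on synthetic chromosomes, negative-binomial
# transcript counts with planted group shifts, planted cis lncRNAs whose
# per-sample expression is coupled to their partner gene (lognormal noise),
# planted miRNA binding sites (full reverse complement of the miRNA, so the
# alignment and energy gates pass) spliced into 3'UTRs and sponge lncRNAs,
# and decoys at every stage: near-window lncRNAs (gap = window + 1),
# low-correlation neighbors, shared genes without sponge sites, and
# scrambled binding sites.

#' Simulation parameters
#'
#' @param n_genes,n_lnc,n_mirna Feature counts per class.
#' @param samples_per_group Samples in each of the two groups (default 6).
#' @param de_fraction Fraction of features (per class) with a planted group
#'   shift, in addition to the planted pairs/axes.
#' @param lfc_magnitude Planted |log2 fold change| (default 2).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param coexpr_noise_sd Lognormal sdlog of the lncRNA-partner coupling
#'   noise (default 0.2, keeping planted pairs above the 0.6 correlation
#'   gate).
#' @param planted_axes Number of planted ceRNA axes (default 1).
#' @param n_decoy_shared Shared-gene decoys lacking a sponge site.
#' @param base_mean Median per-sample count of a feature (default 500).
#' @param mrna_length,lnc_length,utr3_length Sequence geometry in nt.
#' @return Named list of parameters.
#' @export
sim_params <- function(n_genes = 200L, n_lnc = 50L, n_mirna = 30L,
                       samples_per_group = 6L, de_fraction = 0.1,
                       lfc_magnitude = 2, nb_dispersion = 0.05,
                       coexpr_noise_sd = 0.2, planted_axes = 1L,
                       n_decoy_shared = 5L, base_mean = 500,
                       mrna_length = 1500L, lnc_length = 800L,
                       utr3_length = 500L) {
  stopifnot(n_genes > 0, n_lnc > 0, n_mirna > 0, samples_per_group > 0,
            de_fraction >= 0, de_fraction < 1, lfc_magnitude > 0,
            nb_dispersion >= 0, planted_axes >= 0)
  needed_lnc <- planted_axes + n_decoy_shared + 4L # + near-window, low-corr, 2 plain cis
  if (n_lnc < needed_lnc) cx_abort(sprintf("n_lnc must be at least %d", needed_lnc))
  if (n_genes < planted_axes + n_decoy_shared + 10L) {
    cx_abort("n_genes too small for the planted structure")
  }
  as.list(environment())
}

#' @noRd
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 9973) %% 2147483647)
}

#' @noRd
random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# codon sampler with strong positional bias so the Fickett TESTCODE
# component votes coding; stop codons are rejected
#' @noRd
biased_cds <- function(n_codons) {
  p1 <- c(A = 0.2, C = 0.2, G = 0.5, T = 0.1)
  p2 <- c(A = 0.4, C = 0.2, G = 0.1, T = 0.3)
  p3 <- c(A = 0.1, C = 0.4, G = 0.1, T = 0.4)
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste0(sample(names(p1), 1, prob = p1),
                   sample(names(p2), 1, prob = p2),
                   sample(names(p3), 1, prob = p3))
      if (!cd %in% stops) break
    }
    codons[i] <- cd
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

#' @noRd
splice_site <- function(seq, site, at) {
  # overwrite (not insert) so transcript length is unchanged
  paste0(substr(seq, 1, at - 1), site,
         substr(seq, at + nchar(site), nchar(seq)))
}

#' @noRd
nb_draw <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a two-group whole-transcriptome experiment
#'
#' Generates annotation, transcript and miRNA sequences, count tables and a
#' design, together with the planted truth set. Identical seeds give
#' identical outputs.
#'
#' @param params Parameter list from [sim_params()].
#' @param seed Integer seed; all randomness derives from it via per-stage
#'   derived seeds.
#' @return A `cx_sim` object: `annotation`, `seqs`, `mirna_seqs`,
#'   `counts_rna`, `counts_mirna`, `design`, `truth`, `params`, `seed`.
#' @export
simulate_transcriptome <- function(params = sim_params(), seed = 1L) {
  p <- params
  n_samples <- 2L * p$samples_per_group
  design <- tibble::tibble(
    sample_id = c(sprintf("L%02d", seq_len(p$samples_per_group)),
                  sprintf("H%02d", seq_len(p$samples_per_group))),
    group = rep(c("L", "H"), each = p$samples_per_group)
  )

  # ---- layout: genes on synthetic chromosomes -------------------------------
  set.seed(stage_seed(seed, 1L))
  gene_ids <- sprintf("G%04d", seq_len(p$n_genes))
  chroms <- paste0("chr", 1:4)
  gene_chrom <- chroms[(seq_len(p$n_genes) - 1L) %% 4L + 1L]
  slot <- (seq_len(p$n_genes) - 1L) %/% 4L
  gene_start <- 50001L + slot * 100000L
  gene_end <- gene_start + 2000L
  gene_strand <- sample(c("+", "-"), p$n_genes, replace = TRUE)

  # planted roles
  n_axes <- p$planted_axes
  axis_gene <- gene_ids[seq_len(n_axes)]
  decoy_gene <- gene_ids[n_axes + seq_len(p$n_decoy_shared)]
  plain_cis_gene <- gene_ids[n_axes + p$n_decoy_shared + 1:2]
  lowcorr_gene <- gene_ids[n_axes + p$n_decoy_shared + 3L] # stays non-DE
  nearwin_gene <- gene_ids[n_axes + p$n_decoy_shared + 4L]
  scrambled_gene <- gene_ids[n_axes + p$n_decoy_shared + 5L]
  cis_partner_gene <- c(axis_gene, decoy_gene, plain_cis_gene)

  lnc_ids <- sprintf("L%04d", seq_len(p$n_lnc))
  axis_lnc <- lnc_ids[seq_len(n_axes)]
  decoy_lnc <- lnc_ids[n_axes + seq_len(p$n_decoy_shared)]
  plain_cis_lnc <- lnc_ids[n_axes + p$n_decoy_shared + 1:2]
  lowcorr_lnc <- lnc_ids[n_axes + p$n_decoy_shared + 3L]
  nearwin_lnc <- lnc_ids[n_axes + p$n_decoy_shared + 4L]
  cis_lnc <- c(axis_lnc, decoy_lnc, plain_cis_lnc)
  cis_partner <- setNames(cis_partner_gene, cis_lnc)

  # lncRNA placement: planted cis lncRNAs sit upstream of their partner
  # (gap within the 10 kb window); the near-window decoy sits at gap
  # window + 1; the rest go to empty slots far from any gene
  lnc_chrom <- character(p$n_lnc)
  lnc_start <- integer(p$n_lnc)
  lnc_strand <- sample(c("+", "-"), p$n_lnc, replace = TRUE)
  lnc_len_genomic <- 1200L
  place_near <- function(gid, gap) {
    gi <- match(gid, gene_ids)
    if (gene_strand[gi] == "+") {
      st <- gene_start[gi] - gap - lnc_len_genomic
    } else {
      st <- gene_end[gi] + gap
    }
    c(match(gene_chrom[gi], chroms), st)
  }
  for (i in seq_len(p$n_lnc)) {
    id <- lnc_ids[i]
    if (id %in% names(cis_partner)) {
      gap <- sample(1000:8000, 1)
      pn <- place_near(cis_partner[[id]], gap)
    } else if (id == nearwin_lnc) {
      pn <- place_near(nearwin_gene, 10001L)
    } else if (id == lowcorr_lnc) {
      pn <- place_near(lowcorr_gene, sample(1000:8000, 1))
    } else {
      # far intergenic: halfway between gene slots (>= 40 kb from any gene)
      gi <- sample(p$n_genes, 1)
      pn <- c(match(gene_chrom[gi], chroms), gene_start[gi] + 50000L)
    }
    lnc_chrom[i] <- chroms[pn[1]]
    lnc_start[i] <- max(1L, pn[2])
  }

  annotation <- dplyr::bind_rows(
    tibble::tibble(
      transcript_id = gene_ids, gene_id = gene_ids, chrom = gene_chrom,
      strand = gene_strand, start = gene_start, end = gene_end,
      biotype = "mRNA", novel = FALSE
    ),
    tibble::tibble(
      transcript_id = lnc_ids, gene_id = lnc_ids, chrom = lnc_chrom,
      strand = lnc_strand, start = lnc_start, end = lnc_start + lnc_len_genomic,
      biotype = "lncRNA", novel = FALSE
    )
  )
  # a subset of non-planted transcripts is marked novel with unknown biotype
  # so the coding-potential classifier is exercised end to end
  planted_ids <- c(cis_lnc, lowcorr_lnc, nearwin_lnc, cis_partner_gene,
                   lowcorr_gene, nearwin_gene, scrambled_gene)
  candidates <- setdiff(annotation$transcript_id, planted_ids)
  novel_ids <- sample(candidates, min(20L, length(candidates)))
  annotation$novel[annotation$transcript_id %in% novel_ids] <- TRUE
  annotation$biotype[annotation$transcript_id %in% novel_ids] <- "unknown"

  # ---- miRNAs ---------------------------------------------------------------
  set.seed(stage_seed(seed, 2L))
  mirna_ids <- sprintf("M%03d", seq_len(p$n_mirna))
  # fixed composition (12 G/C of 22) keeps every planted full-complement
  # duplex comfortably below the -45 kcal/mol alignment-energy gate
  mirna_seqs <- setNames(
    vapply(seq_len(p$n_mirna), function(i) {
      paste(sample(c(rep("G", 6), rep("C", 6), rep("A", 5), rep("U", 5))),
            collapse = "")
    }, character(1)),
    mirna_ids
  )
  axis_mirna <- mirna_ids[seq_len(n_axes)]
  # decoy shared genes are targeted by other DE miRNAs (or the axis miRNA)
  decoy_mirna_pool <- mirna_ids[n_axes + 1:3]
  decoy_mirna <- decoy_mirna_pool[(seq_len(p$n_decoy_shared) - 1L) %% 3L + 1L]

  # ---- DE assignment --------------------------------------------------------
  set.seed(stage_seed(seed, 3L))
  pick_de <- function(ids, forced_up, forced_down, frac) {
    free <- setdiff(ids, c(forced_up, forced_down))
    extra <- sample(free, round(frac * length(ids)))
    dir_extra <- sample(c("Up", "Down"), length(extra), replace = TRUE)
    tibble::tibble(
      feature_id = c(forced_up, forced_down, extra),
      direction = c(rep("Up", length(forced_up)), rep("Down", length(forced_down)),
                    dir_extra)
    )
  }
  # planted directions are kept roughly balanced so total-count
  # normalization is not skewed by the planted set itself
  de_genes <- pick_de(gene_ids,
                      forced_up = c(axis_gene, plain_cis_gene[1], scrambled_gene),
                      forced_down = c(decoy_gene, plain_cis_gene[2]),
                      frac = p$de_fraction)
  de_lncs <- pick_de(lnc_ids,
                     forced_up = c(axis_lnc, plain_cis_lnc[1]),
                     forced_down = c(decoy_lnc, plain_cis_lnc[2],
                                     lowcorr_lnc, nearwin_lnc),
                     frac = p$de_fraction)
  de_mirnas <- pick_de(mirna_ids,
                       forced_up = character(),
                       forced_down = unique(c(axis_mirna, decoy_mirna)),
                       frac = p$de_fraction)
  # planted cis lncRNAs inherit their partner's realized counts, so their
  # direction is the partner's; align the truth table accordingly
  dir_gene_map <- setNames(de_genes$direction, de_genes$feature_id)
  for (ln in cis_lnc) {
    gd <- dir_gene_map[[cis_partner[[ln]]]] %||% NA_character_
    de_lncs$direction[de_lncs$feature_id == ln] <- gd
  }

  # ---- sequences ------------------------------------------------------------
  set.seed(stage_seed(seed, 4L))
  n_codons <- (p$mrna_length - p$utr3_length - 100L) %/% 3L - 2L
  site_of <- c(setNames(rep(axis_mirna, length.out = n_axes), axis_gene),
               setNames(decoy_mirna, decoy_gene))
  seqs <- character(0)
  for (i in seq_len(p$n_genes)) {
    gid <- gene_ids[i]
    s <- paste0(random_seq(100L), biased_cds(n_codons), random_seq(p$utr3_length))
    if (gid %in% names(site_of)) {
      site <- chartr("U", "T", rna_revcomp(mirna_seqs[[site_of[[gid]]]]))
      flank <- "GCGCGCGC"
      at <- nchar(s) - p$utr3_length + 100L
      s <- splice_site(s, paste0(flank, site, flank), at)
    }
    if (n_axes >= 1L && gid == scrambled_gene) {
      site <- chartr("U", "T", rna_revcomp(mirna_seqs[[axis_mirna[1]]]))
      scram <- paste(sample(strsplit(site, "")[[1]]), collapse = "")
      at <- nchar(s) - p$utr3_length + 100L
      s <- splice_site(s, scram, at)
    }
    seqs[gid] <- s
  }
  for (i in seq_len(p$n_lnc)) {
    lid <- lnc_ids[i]
    s <- random_seq(p$lnc_length)
    if (lid %in% axis_lnc) {
      site <- chartr("U", "T", rna_revcomp(mirna_seqs[[axis_mirna[match(lid, axis_lnc)]]]))
      s <- splice_site(s, paste0("GCGCGCGC", site, "GCGCGCGC"), nchar(s) %/% 2L)
    }
    seqs[lid] <- s
  }

  # ---- counts ---------------------------------------------------------------
  set.seed(stage_seed(seed, 5L))
  draw_counts <- function(ids, de_tab) {
    base <- rlnorm(length(ids), meanlog = log(p$base_mean), sdlog = 0.5)
    dirs <- setNames(de_tab$direction, de_tab$feature_id)
    out <- matrix(0, nrow = length(ids), ncol = n_samples,
                  dimnames = list(ids, design$sample_id))
    for (i in seq_along(ids)) {
      d <- unname(dirs[ids[i]])
      shift <- if (is.na(d)) 1 else 2^(ifelse(d == "Up", p$lfc_magnitude, -p$lfc_magnitude))
      mu <- ifelse(design$group == "H", base[i] * shift, base[i])
      out[i, ] <- nb_draw(n_samples, mu, p$nb_dispersion)
    }
    out
  }
  counts_gene <- draw_counts(gene_ids, de_genes)
  counts_lnc <- draw_counts(lnc_ids, de_lncs)
  # couple planted cis lncRNAs to their partner's realized counts: the
  # lncRNA expression is the partner profile times lognormal noise, so the
  # pair's per-sample co-expression survives the correlation gate
  for (ln in cis_lnc) {
    partner <- counts_gene[cis_partner[[ln]], ]
    counts_lnc[ln, ] <- round(pmax(partner, 1) *
                                rlnorm(n_samples, 0, p$coexpr_noise_sd))
  }
  counts_rna <- dplyr::bind_cols(
    tibble::tibble(feature_id = c(gene_ids, lnc_ids)),
    tibble::as_tibble(rbind(counts_gene, counts_lnc))
  )
  attr(counts_rna, "unit") <- "count"
  counts_mirna <- dplyr::bind_cols(
    tibble::tibble(feature_id = mirna_ids),
    tibble::as_tibble(draw_counts(mirna_ids, de_mirnas))
  )
  attr(counts_mirna, "unit") <- "count"

  truth <- list(
    de = dplyr::bind_rows(
      dplyr::mutate(de_genes, kind = "gene"),
      dplyr::mutate(de_lncs, kind = "lncRNA"),
      dplyr::mutate(de_mirnas, kind = "miRNA")
    ),
    cis_pairs = tibble::tibble(lnc_id = cis_lnc,
                               mrna_id = unname(cis_partner[cis_lnc])),
    sites = dplyr::bind_rows(
      tibble::tibble(mirna_id = unname(site_of), target_id = names(site_of),
                     kind = "gene"),
      tibble::tibble(mirna_id = axis_mirna, target_id = axis_lnc, kind = "sponge")
    ),
    axes = tibble::tibble(lnc_id = axis_lnc, mirna_id = axis_mirna,
                          gene_id = axis_gene),
    decoys = tibble::tibble(
      id = c(nearwin_lnc, lowcorr_lnc, decoy_gene, scrambled_gene),
      type = c("near_window_lnc", "low_correlation_lnc",
               rep("shared_gene_no_sponge", length(decoy_gene)),
               "scrambled_site_gene")
    )
  )

  structure(
    list(annotation = annotation, seqs = seqs, mirna_seqs = mirna_seqs,
         counts_rna = counts_rna, counts_mirna = counts_mirna,
         design = design, truth = truth, params = p, seed = seed),
    class = "cx_sim"
  )
}

#' @export
print.cx_sim <- function(x, ...) {
  cat(sprintf("<cx_sim> seed %d: %d genes, %d lncRNAs, %d miRNAs, %d+%d samples\n",
              x$seed, x$params$n_genes, x$params$n_lnc, x$params$n_mirna,
              x$params$samples_per_group, x$params$samples_per_group))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits exactly the formats the readers consume: GTF annotation, FASTA
#' transcript and miRNA sequences, count TSVs, design TSV and the truth set
#' as JSON.
#'
#' @param sim A `cx_sim` object.
#' @param dir Output directory (created if absent).
#' @return Named character vector of paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cx_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotation = file.path(dir, "annotation.gtf"),
    transcripts = file.path(dir, "transcripts.fa"),
    mirnas = file.path(dir, "mirnas.fa"),
    counts_rna = file.path(dir, "counts_rna.tsv"),
    counts_mirna = file.path(dir, "counts_mirna.tsv"),
    design = file.path(dir, "design.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_annotation(sim$annotation, paths["annotation"])
  write_sequences(sim$seqs, paths["transcripts"])
  write_sequences(sim$mirna_seqs, paths["mirnas"])
  write_expression(sim$counts_rna, paths["counts_rna"])
  write_expression(sim$counts_mirna, paths["counts_mirna"])
  readr::write_tsv(sim$design, paths["design"], progress = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], dataframe = "rows")
  invisible(paths)
}

#' Confusion metrics for one recovery stage
#'
#' @param found Character vector of ids called positive.
#' @param planted Character vector of true positive ids.
#' @return One-row tibble with `tp`, `fp`, `fn`, `sensitivity`, `precision`
#'   (`NA` when nothing was called).
#' @export
recovery_metrics <- function(found, planted) {
  tp <- length(intersect(found, planted))
  fp <- length(setdiff(found, planted))
  fn <- length(setdiff(planted, found))
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  )
}

#' Per-stage recovery of a pipeline run against the planted truth
#'
#' DE calls count as recovered only when the called direction matches the
#' planted direction; pairs, sites and axes are matched on their id tuples.
#'
#' @param run A `cx_run` pipeline result (see [run_pipeline()]).
#' @param truth Truth list from [simulate_transcriptome()].
#' @return Tibble with one row per stage (`de`, `cis`, `sites`, `axes`).
#' @export
evaluate_recovery <- function(run, truth) {
  de_all <- dplyr::bind_rows(run$de$rna, run$de$mirna)
  found_de <- paste(de_all$feature_id[de_all$significant],
                    de_all$direction[de_all$significant])
  planted_de <- paste(truth$de$feature_id, truth$de$direction)
  key <- function(...) paste(..., sep = "|")
  out <- dplyr::bind_rows(
    de = recovery_metrics(found_de, planted_de),
    cis = recovery_metrics(key(run$cis_pairs$lnc_id, run$cis_pairs$mrna_id),
                           key(truth$cis_pairs$lnc_id, truth$cis_pairs$mrna_id)),
    sites = recovery_metrics(
      key(c(run$gene_sites$mirna_id[run$gene_sites$passes],
            run$sponge_sites$mirna_id[run$sponge_sites$passes]),
          c(run$gene_sites$target_id[run$gene_sites$passes],
            run$sponge_sites$target_id[run$sponge_sites$passes])),
      key(truth$sites$mirna_id, truth$sites$target_id)
    ),
    axes = recovery_metrics(key(run$axes$lnc_id, run$axes$mirna_id, run$axes$gene_id),
                            key(truth$axes$lnc_id, truth$axes$mirna_id,
                                truth$axes$gene_id)),
    .id = "stage"
  )
  out
}
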