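# Orchestration: classify -> differential expression -> cis pairs ->
# miRNA sites -> networks -> axis nomination, with a funnel report of
# feature counts surviving each gate. Reruns on identical inputs are
# byte-identical.

#' Pipeline configuration
#'
#' Every gate of the analysis is a named key defaulting to its conventional
#' printed value, so deviations are explicit.
#'
#' @param fc_threshold,q_threshold DE gates (|FC| >= 2, Q <= 0.001).
#' @param corr_threshold Dual correlation gate (0.6).
#' @param up_window,down_window Cis windows in nt (10 kb / 20 kb).
#' @param hybrid_mfe_max,align_mfe_max Site energy gates in kcal/mol
#'   (-30, -45).
#' @param score_gate Alignment score gate; default is the internal
#'   calibration of the external 300 gate (see [calibrated_score_gate()]).
#' @param trans_mfe_max Trans-candidate duplex gate in kcal/mol (-30).
#' @param site_window,site_step Target-scan window geometry in nt.
#' @param pseudo Pseudo-expression added before the log2 ratio.
#' @return Named list of configuration values.
#' @export
cerna_config <- function(fc_threshold = 2, q_threshold = 0.001,
                         corr_threshold = 0.6,
                         up_window = 10000, down_window = 20000,
                         hybrid_mfe_max = -30, align_mfe_max = -45,
                         score_gate = calibrated_score_gate(),
                         trans_mfe_max = -30,
                         site_window = 30L, site_step = 5L,
                         pseudo = 0.1) {
  as.list(environment())
}

#' Run the full ceRNA-axis discovery pipeline
#'
#' Executes biotype classification, differential expression (transcripts
#' and miRNAs), cis-pair construction, miRNA target and sponge scanning,
#' network construction/intersection and axis nomination on a simulated or
#' assembled experiment.
#'
#' @param data A `cx_sim` object, or any list with elements `annotation`,
#'   `seqs`, `mirna_seqs`, `counts_rna`, `counts_mirna`, `design`.
#' @param config Configuration from [cerna_config()].
#' @param outdir Optional output directory; when given, all stage tables,
#'   SIF networks and the run report are written there deterministically.
#' @param coding_scores Optional external coding-potential score table
#'   passed to [classify_transcripts()].
#' @return A `cx_run` object: DE results, cis pairs, site tables, networks,
#'   shared genes, axis candidates and the gate funnel.
#' @export
run_pipeline <- function(data, config = cerna_config(), outdir = NULL,
                         coding_scores = NULL) {
  stages <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cx_abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # classify ------------------------------------------------------------------
  annotation <- run_stage("classify", classify_transcripts(
    data$annotation, seqs = data$seqs, scores = coding_scores
  ))
  lnc_ids <- annotation$transcript_id[annotation$biotype == "lncRNA"]
  mrna_ids <- annotation$transcript_id[annotation$biotype == "mRNA"]

  # differential expression ---------------------------------------------------
  de_rna <- run_stage("diffexpr", diff_expression(
    data$counts_rna, data$design,
    fc_threshold = config$fc_threshold, q_threshold = config$q_threshold,
    pseudo = config$pseudo
  ))
  de_mirna <- run_stage("diffexpr", diff_expression(
    data$counts_mirna, data$design,
    fc_threshold = config$fc_threshold, q_threshold = config$q_threshold,
    pseudo = config$pseudo
  ))
  de_lnc <- de_rna[de_rna$feature_id %in% lnc_ids, ]
  de_mrna <- de_rna[de_rna$feature_id %in% mrna_ids, ]

  # expression for the correlation gate (FPKM from counts + lengths) ----------
  lengths <- setNames(nchar(data$seqs), names(data$seqs))
  expr_fpkm <- run_stage("fpkm", fpkm(data$counts_rna, lengths))

  # cis pairs -----------------------------------------------------------------
  cis_pairs <- run_stage("cis", build_cis_pairs(
    annotation, expr_fpkm, de_lnc, de_mrna,
    up_window = config$up_window, down_window = config$down_window,
    corr_threshold = config$corr_threshold
  ))

  # miRNA site scanning -------------------------------------------------------
  thr <- site_thresholds(score_gate = config$score_gate,
                         align_mfe_max = config$align_mfe_max,
                         hybrid_mfe_max = config$hybrid_mfe_max)
  des_ids <- de_mirna$feature_id[de_mirna$significant]
  scan_many <- function(target_ids) {
    purrr::map(des_ids, function(mid) {
      purrr::map(target_ids, function(tid) {
        scan_targets(data$mirna_seqs[[mid]], data$seqs[[tid]], thresholds = thr,
                     mirna_id = mid, target_id = tid,
                     window = config$site_window, step = config$site_step)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }
  gene_sites <- run_stage("mirna", scan_many(mrna_ids))
  del_ids <- de_lnc$feature_id[de_lnc$significant]
  sponge_sites <- run_stage("mirna", scan_many(del_ids))

  # networks and axes ----------------------------------------------------------
  del_deg <- run_stage("network", build_del_deg_networks(cis_pairs, de_lnc, de_mrna))
  des_deg <- run_stage("network", build_des_deg_network(gene_sites, de_mirna, de_mrna))
  shared <- shared_genes(list(del_deg$up, del_deg$down), des_deg)
  axes <- run_stage("axes", nominate_axes(
    shared, cis_pairs, gene_sites, sponge_sites, de_lnc, de_mirna, de_mrna
  ))

  funnel <- tibble::tibble(
    stage = c("transcripts", "lncRNA", "mRNA", "miRNA",
              "DEL", "DEM", "DES",
              "cis_pairs", "cis_pairs_de_mrna",
              "gene_sites_passing", "sponge_sites_passing",
              "network_edges_up", "network_edges_down", "network_edges_mirna",
              "shared_genes", "axes", "axes_consistent"),
    n = c(nrow(annotation), length(lnc_ids), length(mrna_ids), nrow(de_mirna),
          sum(de_lnc$significant), sum(de_mrna$significant),
          sum(de_mirna$significant),
          nrow(cis_pairs), sum(cis_pairs$mrna_is_de),
          sum(gene_sites$passes), sum(sponge_sites$passes),
          nrow(del_deg$up$edges), nrow(del_deg$down$edges),
          nrow(des_deg$edges),
          length(shared), nrow(axes), sum(axes$consistent))
  )

  run <- structure(
    list(annotation = annotation,
         de = list(rna = de_rna, lnc = de_lnc, mrna = de_mrna, mirna = de_mirna),
         cis_pairs = cis_pairs, gene_sites = gene_sites,
         sponge_sites = sponge_sites,
         networks = list(up = del_deg$up, down = del_deg$down, mirna = des_deg),
         shared = shared, axes = axes, funnel = funnel, config = config,
         seed = data$seed %||% NA_integer_,
         version = as.character(utils::packageVersion("cernaxis"))),
    class = "cx_run"
  )
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' Run the pipeline from files on disk
#'
#' @param annotation,transcripts,mirnas,counts_rna,counts_mirna,design File
#'   paths (GTF, FASTA, FASTA, TSV, TSV, TSV respectively).
#' @inheritParams run_pipeline
#' @return A `cx_run` object.
#' @export
run_pipeline_files <- function(annotation, transcripts, mirnas,
                               counts_rna, counts_mirna, design,
                               config = cerna_config(), outdir = NULL,
                               coding_scores = NULL) {
  des <- read_design(design)
  data <- list(
    annotation = read_annotation(annotation),
    seqs = read_sequences(transcripts),
    mirna_seqs = read_sequences(mirnas, rna = TRUE),
    counts_rna = read_expression(counts_rna, des),
    counts_mirna = read_expression(counts_mirna, des),
    design = des
  )
  run_pipeline(data, config = config, outdir = outdir, coding_scores = coding_scores)
}

#' @noRd
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  num6 <- function(df) dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                                       ~ round(.x, 6)))
  readr::write_tsv(num6(tidy(run$de$rna)), file.path(outdir, "de_transcripts.tsv"),
                   progress = FALSE)
  readr::write_tsv(num6(tidy(run$de$mirna)), file.path(outdir, "de_mirna.tsv"),
                   progress = FALSE)
  readr::write_tsv(num6(run$cis_pairs), file.path(outdir, "cis_pairs.tsv"),
                   progress = FALSE)
  readr::write_tsv(num6(run$gene_sites), file.path(outdir, "mirna_sites.tsv"),
                   progress = FALSE)
  readr::write_tsv(num6(run$sponge_sites), file.path(outdir, "sponge_sites.tsv"),
                   progress = FALSE)
  write_network(run$networks$up, file.path(outdir, "network_up"))
  write_network(run$networks$down, file.path(outdir, "network_down"))
  write_network(run$networks$mirna, file.path(outdir, "network_mirna"))
  jsonlite::write_json(
    list(funnel = run$funnel, thresholds = run$config,
         seed = run$seed, version = run$version,
         axes = num6(run$axes)),
    file.path(outdir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(outdir)
}

#' @export
print.cx_run <- function(x, ...) {
  cat("<cx_run> gate funnel:\n")
  print(x$funnel, n = nrow(x$funnel))
  invisible(x)
}

#' @method tidy cx_run
#' @export
tidy.cx_run <- function(x, ...) tibble::as_tibble(x$axes)

#' @method glance cx_run
#' @export
glance.cx_run <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$funnel, names_from = "stage", values_from = "n")
  tibble::as_tibble(wide)
}

#' Gate-funnel plot of a pipeline run
#'
#' @param object A `cx_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cx_run
#' @export
autoplot.cx_run <- function(object, ...) {
  dat <- object$funnel
  dat$stage <- factor(dat$stage, levels = rev(dat$stage))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.2, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.15))) +
    ggplot2::labs(x = "features surviving", y = NULL) +
    ggplot2::theme_minimal()
}
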