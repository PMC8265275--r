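# Regulatory network construction and ceRNA axis nomination.
#
# Two co-directional cis networks (up-regulated lncRNAs with up-regulated
# target genes, and the down-down counterpart) are intersected with the
# miRNA-target network on shared genes; a shared gene becomes an axis
# candidate when some cis-paired lncRNA also carries a passing binding site
# (sponge site) for a miRNA that targets the gene. The ceRNA expectation is
# lncRNA and gene co-directional with the miRNA antiparallel; candidates
# violating it are reported with `consistent = FALSE` rather than dropped.

#' @noRd
de_direction_map <- function(de) setNames(de$direction, de$feature_id)

#' @noRd
de_lfc_map <- function(de) setNames(de$log2fc, de$feature_id)

#' Build the co-directional cis networks
#'
#' Splits DE-flagged cis pairs into an up-up and a down-down network; pairs
#' with discordant directions belong to neither.
#'
#' @param cis_pairs Cis pair tibble from [build_cis_pairs()] (only pairs
#'   with `mrna_is_de` are used).
#' @param de_lnc,de_gene DE tibbles providing directions and log2FC for the
#'   lncRNAs and the genes/mRNAs.
#' @return List of two `cx_network` objects, `up` and `down`.
#' @export
build_del_deg_networks <- function(cis_pairs, de_lnc, de_gene) {
  pairs <- dplyr::filter(tibble::as_tibble(cis_pairs), .data$mrna_is_de)
  dir_lnc <- de_direction_map(de_lnc)
  dir_gene <- de_direction_map(de_gene)
  lfc <- c(de_lfc_map(de_lnc), de_lfc_map(de_gene))
  pairs$lnc_dir <- unname(dir_lnc[pairs$lnc_id])
  pairs$gene_dir <- unname(dir_gene[pairs$mrna_id])
  if (anyNA(pairs$lnc_dir) || anyNA(pairs$gene_dir)) {
    cx_abort("missing DE direction for a cis pair member")
  }
  one_net <- function(dir) {
    sub <- pairs[pairs$lnc_dir == dir & pairs$gene_dir == dir, ]
    edges <- tibble::tibble(source = sub$lnc_id, interaction = "cis",
                            target = sub$mrna_id, sign = "positive") |>
      dplyr::distinct()
    ids <- unique(c(edges$source, edges$target))
    nodes <- tibble::tibble(
      id = ids,
      kind = ifelse(ids %in% edges$source, "lncRNA", "gene"),
      log2fc = unname(lfc[ids]),
      direction = dir
    )
    cx_network(edges, nodes)
  }
  list(up = one_net("Up"), down = one_net("Down"))
}

#' Build the DE miRNA - DE gene target network
#'
#' One edge per (miRNA, gene) with at least one passing binding site, signed
#' by the DE direction pattern ([pair_sign()]).
#'
#' @param sites Site tibble from [scan_targets()] (rows with `passes` are
#'   used).
#' @param de_mirna,de_gene DE tibbles for the miRNAs and genes; only
#'   significant members enter the network.
#' @return A `cx_network` with `mirna-target` edges.
#' @export
build_des_deg_network <- function(sites, de_mirna, de_gene) {
  sites <- dplyr::filter(tibble::as_tibble(sites), .data$passes)
  dir_mirna <- de_direction_map(de_mirna)
  dir_gene <- de_direction_map(de_gene)
  lfc <- c(de_lfc_map(de_mirna), de_lfc_map(de_gene))
  edges <- sites |>
    dplyr::distinct(.data$mirna_id, .data$target_id) |>
    dplyr::mutate(md = unname(dir_mirna[.data$mirna_id]),
                  gd = unname(dir_gene[.data$target_id])) |>
    dplyr::filter(.data$md %in% c("Up", "Down"), .data$gd %in% c("Up", "Down"))
  if (!nrow(edges)) {
    return(cx_network(
      tibble::tibble(source = character(), interaction = character(),
                     target = character(), sign = character()),
      tibble::tibble(id = character(), kind = character(),
                     log2fc = numeric(), direction = character())
    ))
  }
  edge_tab <- tibble::tibble(source = edges$mirna_id, interaction = "mirna-target",
                             target = edges$target_id,
                             sign = pair_sign(edges$md, edges$gd))
  ids <- unique(c(edge_tab$source, edge_tab$target))
  dirs <- c(dir_mirna, dir_gene)
  nodes <- tibble::tibble(
    id = ids,
    kind = ifelse(ids %in% edge_tab$source, "miRNA", "gene"),
    log2fc = unname(lfc[ids]),
    direction = unname(dirs[ids])
  )
  cx_network(edge_tab, nodes)
}

#' Genes shared between two networks
#'
#' @param netA,netB `cx_network` objects (or lists of them, flattened).
#' @return Sorted character vector of gene ids appearing as edge targets in
#'   both.
#' @export
shared_genes <- function(netA, netB) {
  targets_of <- function(net) {
    if (inherits(net, "cx_network")) net <- list(net)
    unique(unlist(purrr::map(net, function(n) {
      kind <- setNames(n$nodes$kind, n$nodes$id)
      tg <- n$edges$target
      tg[kind[tg] == "gene"]
    })))
  }
  sort(intersect(targets_of(netA), targets_of(netB)))
}

#' Nominate ceRNA axes from shared genes
#'
#' For each gene shared between the cis and miRNA-target networks, every
#' (lncRNA cis-paired to it) x (miRNA targeting it) combination where the
#' lncRNA also carries a passing sponge site for that miRNA becomes an axis
#' candidate. A candidate is `consistent` with the ceRNA expectation when
#' the lncRNA and gene share a direction and the miRNA opposes it.
#' Candidates are sorted by (`consistent` desc, summed |log2FC| desc).
#'
#' @param shared Character vector of shared gene ids (see [shared_genes()]).
#' @param cis_pairs Cis pairs tibble ([build_cis_pairs()]).
#' @param gene_sites miRNA-on-gene site tibble ([scan_targets()]).
#' @param sponge_sites miRNA-on-lncRNA site tibble (target ids are lncRNA
#'   ids).
#' @param de_lnc,de_mirna,de_gene DE tibbles for directions and log2FC.
#' @return Tibble of axis candidates: ids, directions, log2FCs, evidence
#'   site coordinates, `consistent`.
#' @export
nominate_axes <- function(shared, cis_pairs, gene_sites, sponge_sites,
                          de_lnc, de_mirna, de_gene) {
  empty <- tibble::tibble(
    lnc_id = character(), mirna_id = character(), gene_id = character(),
    lnc_dir = character(), mirna_dir = character(), gene_dir = character(),
    lnc_log2fc = numeric(), mirna_log2fc = numeric(), gene_log2fc = numeric(),
    sponge_start = integer(), sponge_end = integer(),
    site_start = integer(), site_end = integer(),
    consistent = logical(), rank_score = numeric()
  )
  if (!length(shared)) return(empty)
  gene_sites <- dplyr::filter(tibble::as_tibble(gene_sites), .data$passes)
  sponge_sites <- dplyr::filter(tibble::as_tibble(sponge_sites), .data$passes)
  cis_pairs <- tibble::as_tibble(cis_pairs)
  dirs <- list(lnc = de_direction_map(de_lnc), mirna = de_direction_map(de_mirna),
               gene = de_direction_map(de_gene))
  lfcs <- list(lnc = de_lfc_map(de_lnc), mirna = de_lfc_map(de_mirna),
               gene = de_lfc_map(de_gene))
  cand <- cis_pairs |>
    dplyr::filter(.data$mrna_id %in% shared) |>
    dplyr::select(lnc_id = "lnc_id", gene_id = "mrna_id") |>
    dplyr::inner_join(
      dplyr::select(gene_sites, mirna_id = "mirna_id", gene_id = "target_id",
                    site_start = "target_start", site_end = "target_end"),
      by = "gene_id", relationship = "many-to-many"
    ) |>
    dplyr::inner_join(
      dplyr::select(sponge_sites, mirna_id = "mirna_id", lnc_id = "target_id",
                    sponge_start = "target_start", sponge_end = "target_end"),
      by = c("lnc_id", "mirna_id"), relationship = "many-to-many"
    ) |>
    dplyr::distinct(.data$lnc_id, .data$mirna_id, .data$gene_id, .keep_all = TRUE)
  if (!nrow(cand)) return(empty)
  cand |>
    dplyr::mutate(
      lnc_dir = unname(dirs$lnc[.data$lnc_id]),
      mirna_dir = unname(dirs$mirna[.data$mirna_id]),
      gene_dir = unname(dirs$gene[.data$gene_id]),
      lnc_log2fc = unname(lfcs$lnc[.data$lnc_id]),
      mirna_log2fc = unname(lfcs$mirna[.data$mirna_id]),
      gene_log2fc = unname(lfcs$gene[.data$gene_id]),
      consistent = .data$lnc_dir == .data$gene_dir & .data$mirna_dir != .data$gene_dir,
      rank_score = abs(.data$lnc_log2fc) + abs(.data$mirna_log2fc) + abs(.data$gene_log2fc)
    ) |>
    dplyr::arrange(dplyr::desc(.data$consistent), dplyr::desc(.data$rank_score)) |>
    dplyr::select(dplyr::all_of(names(empty)))
}
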