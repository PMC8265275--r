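# Network export for Cytoscape-class viewers: a SIF edge file (source,
# interaction-type, target) plus a node-attribute TSV. Row order is
# lexicographic so repeated exports are byte-identical.

#' Construct a regulatory network object
#'
#' Edges are typed (`cis`: lncRNA -> gene, `mirna-target`: miRNA -> gene,
#' `sponge`: lncRNA -> miRNA) and optionally signed by the direction pattern
#' of the two members.
#'
#' @param edges Tibble with columns `source`, `interaction`, `target` and
#'   optionally `sign` (`positive`/`negative`/`none`).
#' @param nodes Tibble with columns `id`, `kind` (`lncRNA`/`miRNA`/`gene`) and
#'   optionally `log2fc`, `direction`.
#' @return A `cx_network` object (list of `edges` and `nodes` tibbles).
#' @export
cx_network <- function(edges, nodes) {
  edges <- tibble::as_tibble(edges)
  nodes <- tibble::as_tibble(nodes)
  if (!"sign" %in% names(edges)) edges$sign <- "none"
  stopifnot(all(c("source", "interaction", "target") %in% names(edges)),
            all(c("id", "kind") %in% names(nodes)))
  if (any(edges$source == edges$target)) cx_abort("self-edges are not allowed")
  unknown <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(unknown)) {
    cx_abort(sprintf("edge references unknown node(s): %s",
                     paste(head(unknown, 5), collapse = ", ")))
  }
  ok_kind <- list(`cis` = c("lncRNA", "gene"),
                  `mirna-target` = c("miRNA", "gene"),
                  `sponge` = c("lncRNA", "miRNA"))
  kind_of <- setNames(nodes$kind, nodes$id)
  for (i in seq_len(nrow(edges))) {
    expect <- ok_kind[[edges$interaction[i]]]
    if (is.null(expect)) cx_abort(sprintf("unknown interaction type '%s'", edges$interaction[i]))
    got <- c(kind_of[[edges$source[i]]], kind_of[[edges$target[i]]])
    if (!identical(unname(got), expect)) {
      cx_abort(sprintf("edge %s -[%s]-> %s violates the bipartite node-kind rule",
                       edges$source[i], edges$interaction[i], edges$target[i]))
    }
  }
  structure(list(edges = edges, nodes = nodes), class = "cx_network")
}

#' @export
print.cx_network <- function(x, ...) {
  cat(sprintf("<cx_network> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  print(dplyr::count(x$edges, .data$interaction, .data$sign))
  invisible(x)
}

#' Export a regulatory network as SIF + node-attribute TSV
#'
#' @param network A `cx_network` object.
#' @param prefix Output path prefix; writes `<prefix>.sif` and
#'   `<prefix>.nodes.tsv`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_network <- function(network, prefix) {
  stopifnot(inherits(network, "cx_network"))
  edges <- dplyr::arrange(network$edges, .data$source, .data$interaction, .data$target)
  nodes <- dplyr::arrange(network$nodes, .data$id)
  sif_path <- paste0(prefix, ".sif")
  node_path <- paste0(prefix, ".nodes.tsv")
  writeLines(paste(edges$source, edges$interaction, edges$target), sif_path)
  if (!"log2fc" %in% names(nodes)) nodes$log2fc <- NA_real_
  if (!"direction" %in% names(nodes)) nodes$direction <- NA_character_
  readr::write_tsv(dplyr::select(nodes, "id", "kind", "log2fc", "direction"),
                   node_path, progress = FALSE)
  invisible(c(sif = sif_path, nodes = node_path))
}

#' Plot a regulatory network
#'
#' A simple bipartite-style layout: node kinds on vertical bands, edges
#' coloured by sign.
#'
#' @param object A `cx_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cx_network
#' @export
autoplot.cx_network <- function(object, ...) {
  nodes <- object$nodes
  band <- c(lncRNA = 0, miRNA = 1, gene = 2)
  nodes <- nodes |>
    dplyr::group_by(.data$kind) |>
    dplyr::mutate(x = band[.data$kind[1]],
                  y = seq_len(dplyr::n()) / (dplyr::n() + 1)) |>
    dplyr::ungroup()
  pos <- dplyr::select(nodes, "id", "x", "y")
  edges <- object$edges |>
    dplyr::left_join(pos, by = c(source = "id")) |>
    dplyr::left_join(pos, by = c(target = "id"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                   colour = .data$sign),
      alpha = 0.6
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, shape = .data$kind),
                        size = 2) +
    ggplot2::scale_x_continuous(breaks = unname(band), labels = names(band)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
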