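# Writers for the network and result tables. All outputs are sorted so
# repeated runs diff cleanly.

#' Write a network as a TSV edge list
#'
#' Rows are sorted by (mirna, gene); provenance labels are joined with ";".
#'
#' @param net A `regulatory_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  e <- net$edges
  ord <- order(e$mirna, e$gene)
  out <- data.frame(
    mirna = e$mirna[ord],
    gene = e$gene[ord],
    sources = vapply(e$sources[ord], paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network in SIF format
#'
#' One row per edge: `mirna<TAB>targets<TAB>gene`, consumable by standard
#' network viewers.
#'
#' @inheritParams write_edge_list
#' @export
write_network_sif <- function(net, path) {
  e <- net$edges
  ord <- order(e$mirna, e$gene)
  lines <- sprintf("%s\ttargets\t%s", e$mirna[ord], e$gene[ord])
  writeLines(lines, path)
  invisible(path)
}

#' Convert a regulatory network to an igraph object
#'
#' Nodes carry a `kind` attribute (`"mirna"` or `"gene"`); edges carry a
#' `sources` attribute (";"-joined provenance labels) and, optionally, a
#' logical `unique` attribute for subnetwork exports.
#'
#' @param net A `regulatory_network`.
#' @param unique_flags Optional logical vector, one per edge row, marking
#'   edges to an exclusively-regulated gene.
#' @return A directed `igraph` graph.
#' @export
as_network_igraph <- function(net, unique_flags = NULL) {
  e <- net$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$mirna, to = e$gene,
               sources = vapply(e$sources, paste, character(1), collapse = ";"),
               stringsAsFactors = FALSE),
    directed = TRUE
  )
  kind <- ifelse(igraph::V(g)$name %in% e$mirna, "mirna", "gene")
  g <- igraph::set_vertex_attr(g, "kind", value = kind)
  if (!is.null(unique_flags)) {
    g <- igraph::set_edge_attr(g, "unique", value = as.logical(unique_flags))
  }
  g
}

#' Export a network as GraphML
#'
#' @inheritParams as_network_igraph
#' @param path Output path.
#' @export
write_network_graphml <- function(net, path, unique_flags = NULL) {
  g <- as_network_igraph(net, unique_flags)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a differential-expression table as TSV
#'
#' Stable column order; rows sorted by p-value ascending with miRNA ID as
#' tie-break.
#'
#' @param de A data frame from [select_de()].
#' @param path Output path.
#' @export
write_de_table <- function(de, path) {
  ord <- order(de$p_value, de$mirna_id)
  utils::write.table(de[ord, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
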