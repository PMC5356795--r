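#' Normalize a miRNA identifier
#'
#' Reconciles the naming conventions found across target databases and the
#' literature: identifiers are lowercased, a leading species prefix
#' (`"hsa-"`) is stripped, and, if an alias table is supplied, reported
#' names are mapped to their official (miRBase) names. Arm suffixes
#' (`-5p`/`-3p`) and letter/number suffixes are preserved. The function is
#' idempotent: normalizing a normalized ID returns it unchanged.
#'
#' @param raw Character vector of raw miRNA identifiers (non-empty strings).
#' @param alias_table Optional named character vector mapping normalized
#'   reported IDs to normalized official IDs, e.g. the table returned by
#'   [mirna_alias_table()]. Alias values must themselves be fixed points of
#'   the normalization.
#' @return Character vector of normalized identifiers, e.g. `"mir-630"`.
#' @examples
#' normalize_mirna_id("hsa-miR-765")
#' normalize_mirna_id("miR-196b", mirna_alias_table())
#' @export
normalize_mirna_id <- function(raw, alias_table = NULL) {
  if (length(raw) == 0L) return(character(0))
  if (any(is.na(raw)) || any(!nzchar(trimws(raw)))) {
    stop("miRNA identifiers must be non-empty strings", call. = FALSE)
  }
  id <- tolower(trimws(raw))
  id <- sub("^hsa-", "", id)
  if (!is.null(alias_table)) {
    hit <- match(id, names(alias_table))
    id[!is.na(hit)] <- unname(alias_table[hit[!is.na(hit)]])
  }
  id
}

#' Normalize a gene identifier
#'
#' Gene symbols are uppercased and trimmed; no symbol-alias resolution is
#' attempted (the source databases mix conventions, and silent alias
#' resolution would change edge counts unpredictably).
#'
#' @param raw Character vector of gene symbols.
#' @return Uppercased, trimmed character vector.
#' @export
normalize_gene_id <- function(raw) {
  toupper(trimws(raw))
}

#' Construct a bipartite miRNA-mRNA regulatory network
#'
#' The central data structure: a deduplicated, directed edge set
#' miRNA -> gene, with per-edge provenance (which source database(s)
#' contributed the pair). IDs are assumed already normalized; use
#' [read_edge_list()] for raw files.
#'
#' @param mirna Character vector of normalized miRNA IDs (one per edge).
#' @param gene Character vector of normalized gene IDs (one per edge).
#' @param sources Either a single source label applied to every edge, or a
#'   list of character vectors (one per edge).
#' @return An object of class `regulatory_network`: a list with an `edges`
#'   data frame (`mirna`, `gene`, list-column `sources`).
#' @export
regulatory_network <- function(mirna = character(0), gene = character(0),
                               sources = "unspecified") {
  stopifnot(length(mirna) == length(gene))
  n <- length(mirna)
  if (is.character(sources) && length(sources) == 1L) {
    sources <- rep(list(sources), n)
  }
  stopifnot(length(sources) == n)
  key <- paste(mirna, gene, sep = "\r")
  keep <- !duplicated(key)
  if (!all(keep)) {
    # fold provenance of duplicated pairs into the first occurrence
    grp <- split(seq_len(n), key)
    sources <- lapply(grp, function(i) sort(unique(unlist(sources[i]))))
    ord <- match(key[keep], names(grp))
    sources <- sources[ord]
    mirna <- mirna[keep]
    gene <- gene[keep]
  } else {
    sources <- lapply(sources, function(s) sort(unique(s)))
  }
  edges <- data.frame(mirna = mirna, gene = gene, stringsAsFactors = FALSE)
  edges$sources <- sources
  structure(list(edges = edges), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf(
    "Bipartite miRNA-mRNA regulatory network: %d miRNAs, %d genes, %d edges\n",
    length(network_mirnas(x)), length(network_genes(x)), nrow(x$edges)
  ))
  invisible(x)
}

#' Network node accessors
#'
#' @param net A `regulatory_network`.
#' @return Sorted character vector of miRNA (resp. gene) node IDs.
#' @export
network_mirnas <- function(net) sort(unique(net$edges$mirna))

#' @rdname network_mirnas
#' @export
network_genes <- function(net) sort(unique(net$edges$gene))

#' Read a miRNA->gene edge list from a TSV file
#'
#' Parses one source database's export. The dialect names which columns
#' hold the miRNA and the gene, so differently shaped exports can be read
#' without reformatting. Lines starting with `#` are ignored. Rows are
#' normalized ([normalize_mirna_id()], [normalize_gene_id()]),
#' deduplicated, and tagged with `source_label`; malformed rows (empty
#' gene or miRNA field) are dropped with a counted warning. Row order
#' never affects the result.
#'
#' @param path Path to a TSV file with at least two columns.
#' @param source_label Provenance label recorded on every edge.
#' @param dialect List with elements `mirna_col` and `gene_col` (column
#'   names if the file has a header, else column positions) and logical
#'   `header` (default `TRUE`).
#' @param alias_table Optional miRNA alias table, see [normalize_mirna_id()].
#' @return A `regulatory_network`.
#' @export
read_edge_list <- function(path, source_label,
                           dialect = list(mirna_col = "mirna",
                                          gene_col = "gene",
                                          header = TRUE),
                           alias_table = NULL) {
  header <- isTRUE(dialect$header) || is.null(dialect$header)
  df <- tryCatch(
    utils::read.delim(path, header = header, comment.char = "#",
                      stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) NULL
  )
  if (is.null(df) || nrow(df) == 0L) {
    warning(sprintf("edge list '%s' is empty; returning an empty network", path),
            call. = FALSE)
    return(regulatory_network())
  }
  pick <- function(col, what) {
    if (is.numeric(col)) {
      if (col > ncol(df)) stop(sprintf("edge list '%s' has no column %d (%s)",
                                       path, col, what), call. = FALSE)
      df[[col]]
    } else {
      if (!col %in% names(df)) stop(sprintf("edge list '%s' is missing column '%s' (%s)",
                                            path, col, what), call. = FALSE)
      df[[col]]
    }
  }
  mirna_raw <- pick(dialect$mirna_col, "miRNA")
  gene_raw <- pick(dialect$gene_col, "gene")
  bad <- is.na(mirna_raw) | is.na(gene_raw) |
    !nzchar(trimws(mirna_raw)) | !nzchar(trimws(gene_raw))
  if (any(bad)) {
    warning(sprintf("dropped %d malformed row(s) from '%s'", sum(bad), path),
            call. = FALSE)
  }
  if (all(bad)) return(regulatory_network())
  regulatory_network(
    mirna = normalize_mirna_id(mirna_raw[!bad], alias_table),
    gene = normalize_gene_id(gene_raw[!bad]),
    sources = source_label
  )
}

#' Merge regulatory networks from multiple sources
#'
#' Edge sets are unioned; an edge present in several networks keeps the
#' deduplicated union of its provenance labels. The merge is commutative
#' and associative up to provenance ordering (labels are kept sorted).
#'
#' @param nets List of `regulatory_network` objects.
#' @return A `regulatory_network`.
#' @export
merge_networks <- function(nets) {
  stopifnot(is.list(nets))
  nets <- Filter(function(n) nrow(n$edges) > 0L, nets)
  if (length(nets) == 0L) return(regulatory_network())
  edges <- do.call(rbind, lapply(nets, function(n) n$edges[c("mirna", "gene")]))
  sources <- do.call(c, lapply(nets, function(n) n$edges$sources))
  regulatory_network(edges$mirna, edges$gene, sources)
}

# in-degree of every gene; basis of the NOD statistic
gene_indegree <- function(net) {
  table(net$edges$gene)
}

#' Compute NOD (count of exclusively-targeted genes) for one miRNA
#'
#' NOD ("novel out-degree") quantifies a miRNA's independent regulatory
#' power: the number of its target genes regulated by no other miRNA in
#' the network, i.e. targets with network-wide regulatory in-degree
#' exactly 1. A miRNA whose targets are all shared has NOD 0 even if its
#' out-degree is large.
#'
#' @param net A `regulatory_network`.
#' @param mirna_id Normalized miRNA ID present in `net`.
#' @return A list of class `nod_record`: `mirna_id`, `out_degree`, `nod`,
#'   `unique_targets` (character vector), `nod_pvalue` (`NA` until a null
#'   model assigns one, see [nod_null_pvalues()]).
#' @seealso [compute_nod_all()] for all miRNAs in one pass.
#' @export
compute_nod <- function(net, mirna_id) {
  targets <- net$edges$gene[net$edges$mirna == mirna_id]
  if (length(targets) == 0L) {
    stop(sprintf("miRNA '%s' is not present in the network", mirna_id),
         call. = FALSE)
  }
  indeg <- gene_indegree(net)
  uniq <- targets[indeg[targets] == 1L]
  structure(
    list(mirna_id = mirna_id,
         out_degree = length(targets),
         nod = length(uniq),
         unique_targets = sort(uniq),
         nod_pvalue = NA_real_),
    class = "nod_record"
  )
}

#' Compute NOD for every miRNA in the network
#'
#' Single pass over the gene in-degree distribution: every gene with
#' exactly one regulator credits that regulator with one unit of NOD.
#'
#' @param net A `regulatory_network`.
#' @return Data frame with one row per miRNA: `mirna_id`, `out_degree`,
#'   `nod`; sorted by `mirna_id`.
#' @export
compute_nod_all <- function(net) {
  if (nrow(net$edges) == 0L) {
    return(data.frame(mirna_id = character(0), out_degree = integer(0),
                      nod = integer(0), stringsAsFactors = FALSE))
  }
  mirnas <- network_mirnas(net)
  outdeg <- table(net$edges$mirna)
  indeg <- gene_indegree(net)
  unique_gene <- names(indeg)[indeg == 1L]
  uniq_edges <- net$edges$mirna[net$edges$gene %in% unique_gene]
  nod <- table(factor(uniq_edges, levels = mirnas))
  data.frame(
    mirna_id = mirnas,
    out_degree = as.integer(outdeg[mirnas]),
    nod = as.integer(nod[mirnas]),
    stringsAsFactors = FALSE
  )
}

#' Unique-target sets for a set of miRNAs
#'
#' @param net A `regulatory_network`.
#' @param mirna_ids miRNA IDs present in `net`.
#' @return Named list mapping each ID to the sorted character vector of its
#'   exclusively-regulated target genes.
#' @export
unique_targets <- function(net, mirna_ids) {
  indeg <- gene_indegree(net)
  unique_gene <- names(indeg)[indeg == 1L]
  out <- lapply(mirna_ids, function(m) {
    targets <- net$edges$gene[net$edges$mirna == m]
    sort(targets[targets %in% unique_gene])
  })
  names(out) <- mirna_ids
  out
}
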