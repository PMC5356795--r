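#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `set_id<TAB>description<TAB>gene...`.
#' Genes are uppercased (the same convention the regulatory network uses)
#' and deduplicated within each set. The default universe is the union of
#' all genes in the collection; pass `universe` to override (e.g. with the
#' network's gene complement).
#'
#' @param path Path to a GMT file.
#' @param universe Optional character vector overriding the universe.
#' @return An object of class `geneset_collection`: list with `sets`
#'   (named list of `list(description, genes)`) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) {
    list(description = f[2L],
         genes = sort(unique(normalize_gene_id(f[-(1:2)]))))
  })
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(sets, `[[`, "genes"))))
  } else {
    universe <- sort(unique(normalize_gene_id(universe)))
  }
  structure(list(sets = sets, universe = universe),
            class = "geneset_collection")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of seeing
#' at least the observed overlap between the query and the set when
#' drawing `|query|` genes from the universe without replacement
#' (P[X >= overlap]). A generic stand-in for GO/KEGG enrichment tools;
#' the biological conclusions depend on the annotation collection and
#' universe supplied. Benjamini-Hochberg FDR is computed across all
#' tested sets.
#'
#' @param query Character vector of gene IDs; genes outside the universe
#'   are dropped with a warning.
#' @param collection A `geneset_collection` from [read_gmt()].
#' @return Data frame sorted by p-value: `set_id`, `description`,
#'   `overlap_count`, `set_size`, `query_size`, `universe_size`,
#'   `p_value`, `bh_fdr`.
#' @export
hypergeom_ora <- function(query, collection) {
  stopifnot(inherits(collection, "geneset_collection"))
  query <- unique(normalize_gene_id(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside) > 0L) {
    warning(sprintf("%d query gene(s) outside the universe were dropped",
                    length(outside)), call. = FALSE)
    query <- setdiff(query, outside)
  }
  empty <- data.frame(set_id = character(0), description = character(0),
                      overlap_count = integer(0), set_size = integer(0),
                      query_size = integer(0), universe_size = integer(0),
                      p_value = numeric(0), bh_fdr = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(query) == 0L) {
    warning("empty query after universe filtering", call. = FALSE)
    return(empty)
  }
  n_univ <- length(collection$universe)
  n_query <- length(query)
  rows <- lapply(names(collection$sets), function(id) {
    genes <- intersect(collection$sets[[id]]$genes, collection$universe)
    k <- length(intersect(genes, query))
    # P[X >= k], X ~ Hypergeom(white = |set|, black = univ - |set|, drawn = |query|)
    p <- stats::phyper(k - 1L, length(genes), n_univ - length(genes),
                       n_query, lower.tail = FALSE)
    data.frame(set_id = id, description = collection$sets[[id]]$description,
               overlap_count = k, set_size = length(genes),
               query_size = n_query, universe_size = n_univ,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
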