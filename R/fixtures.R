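# Packaged reference tables: a literature catalog of chemoradiotherapy-
# response miRNAs with their network NOD values, and the candidate
# biomarker table of the NOD-based selection they anchor. Both ship as
# plain TSV under extdata; a deterministic toy network realizing the
# catalog's NOD values is built in code.

#' Literature catalog of chemoradiotherapy-response miRNAs
#'
#' Thirty publicly reported miRNAs associated with colorectal-cancer
#' response to preoperative chemoradiotherapy, each annotated with the
#' NOD value it attains in an integrated miRNA-mRNA regulatory network.
#' Reported and official (miRBase-reconciled) names are both kept; the
#' pair feeds [mirna_alias_table()].
#'
#' @return Data frame: `reported_id`, `official_id`, `year`,
#'   `expression_level`, `sample_type`, `nod`.
#' @export
crt_mirna_catalog <- function() {
  path <- system.file("extdata", "crt_mirna_catalog.tsv", package = "pomanet",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c(nod = "integer"))
}

#' miRNA alias table from the packaged catalog
#'
#' Maps normalized reported names to normalized official names for the
#' catalog entries where the two differ (e.g. `mir-196b` ->
#' `mir-196b-5p`), for use with [normalize_mirna_id()].
#'
#' @return Named character vector (possibly empty of identities).
#' @export
mirna_alias_table <- function() {
  cat_df <- crt_mirna_catalog()
  reported <- normalize_mirna_id(cat_df$reported_id)
  official <- normalize_mirna_id(cat_df$official_id)
  keep <- reported != official
  stats::setNames(official[keep], reported[keep])
}

#' Candidate biomarker reference table
#'
#' The nine candidate biomarker miRNAs selected by the NOD-based pipeline,
#' with their DE p-values, network target counts, NOD values and reported
#' NOD p-values. miRNA IDs are normalized on load. Consumed as a fixture:
#' the printed NOD p-values come from the original network, which is not
#' reconstructable from public database snapshots.
#'
#' @return Data frame: `mirna_id`, `de_p_value`, `n_targets`, `nod`,
#'   `nod_p_value`.
#' @export
candidate_biomarker_table <- function() {
  path <- system.file("extdata", "candidate_biomarkers.tsv",
                      package = "pomanet", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$mirna_id <- normalize_mirna_id(df$mirna_id)
  df
}

#' Deterministic toy network realizing the catalog's NOD values
#'
#' Builds a small bipartite network in which each of the 30 catalog
#' miRNAs has exactly its cataloged NOD: a miRNA with NOD v receives v
#' genes reserved for it alone, plus five shared "hub" genes targeted by
#' every miRNA (so NOD < out-degree throughout). Useful as a packaged,
#' dependency-free network for examples and validation.
#'
#' @return A `regulatory_network` with source label `"catalog_toy"`.
#' @export
toy_catalog_network <- function() {
  cat_df <- crt_mirna_catalog()
  ids <- normalize_mirna_id(cat_df$official_id)
  hubs <- sprintf("SHG%02d", 1:5)
  em <- character(0); eg <- character(0)
  next_gene <- 1L
  for (i in seq_along(ids)) {
    v <- cat_df$nod[i]
    uniq <- sprintf("UTG%04d", seq.int(next_gene, length.out = v))
    next_gene <- next_gene + v
    em <- c(em, rep(ids[i], v + length(hubs)))
    eg <- c(eg, uniq, hubs)
  }
  regulatory_network(em, eg, "catalog_toy")
}
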