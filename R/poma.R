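#' Configuration for the POMA candidate-selection pipeline
#'
#' @param de_p_threshold Raw p-value cutoff for the DE stage (default 0.05).
#' @param fc_threshold Linear fold-change cutoff for the DE stage
#'   (default 2).
#' @param nod_alpha Significance level for the NOD null test
#'   (default 0.05).
#' @param null_method `"empirical_tail"` (deterministic network-rank null,
#'   default) or `"rewire_permutation"` (degree-preserving edge rewiring);
#'   see [nod_null_pvalues()].
#' @param n_permutations Number of rewiring permutations (>= 100 for
#'   reported p-values; default 1000). Ignored by `empirical_tail`.
#' @param seed Integer seed controlling the permutation RNG.
#' @param variant t-test variant for the DE stage.
#' @return A list of class `poma_config`.
#' @export
poma_config <- function(de_p_threshold = 0.05, fc_threshold = 2,
                        nod_alpha = 0.05,
                        null_method = c("empirical_tail", "rewire_permutation"),
                        n_permutations = 1000L, seed = 1L,
                        variant = c("student", "welch")) {
  null_method <- match.arg(null_method)
  variant <- match.arg(variant)
  stopifnot(de_p_threshold > 0, de_p_threshold < 1,
            nod_alpha >= 0, nod_alpha < 1, fc_threshold > 0)
  if (null_method == "rewire_permutation" && n_permutations < 100L) {
    stop("use at least 100 permutations for reported p-values", call. = FALSE)
  }
  structure(list(de_p_threshold = de_p_threshold, fc_threshold = fc_threshold,
                 nod_alpha = nod_alpha, null_method = null_method,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), variant = variant),
            class = "poma_config")
}

#' Partition DE miRNAs by network membership
#'
#' DE miRNAs absent from the regulatory network cannot be scored by NOD;
#' they are reported, never silently dropped.
#'
#' @param de A DE table from [select_de()] (only `selected` rows are
#'   mapped) or a character vector of miRNA IDs.
#' @param net A `regulatory_network`.
#' @return List with sorted character vectors `mapped` and `unmapped`.
#' @export
map_de_to_network <- function(de, net) {
  ids <- if (is.data.frame(de)) de$mirna_id[de$selected] else as.character(de)
  ids <- sort(unique(ids))
  in_net <- ids %in% net$edges$mirna
  list(mapped = ids[in_net], unmapped = ids[!in_net])
}

#' NOD significance under an empirical or rewiring null
#'
#' Two null models for "is this miRNA's NOD larger than expected?":
#'
#' * `empirical_tail` — the network-wide NOD distribution is the null;
#'   `p(m) = (1 + #\{miRNAs with NOD >= NOD(m)\}) / (1 + M)` over all `M`
#'   network miRNAs (the focal miRNA included). Deterministic; measures
#'   relative extremeness of NOD within the network, so its resolution is
#'   limited to `2/(M+1)`.
#' * `rewire_permutation` — degree-preserving bipartite edge rewiring;
#'   `p(m) = (1 + #\{permutations with NOD*(m) >= NOD(m)\}) /
#'   (1 + n_permutations)`. Measures exclusivity beyond what the miRNA's
#'   own out-degree and the gene in-degree sequence already imply.
#'
#' Both use +1 smoothing so p is never exactly 0.
#'
#' @param net A `regulatory_network`.
#' @param focal Character vector of miRNA IDs present in `net`.
#' @param method `"empirical_tail"` or `"rewire_permutation"`.
#' @param n_permutations Number of rewiring permutations.
#' @param seed Integer seed (rewiring only).
#' @param swap_factor Swap attempts per permutation, as a multiple of the
#'   edge count (default 10; enough mixing for sparse regulatory graphs).
#' @return Named numeric vector of p-values, one per focal miRNA.
#' @export
nod_null_pvalues <- function(net, focal,
                             method = c("empirical_tail", "rewire_permutation"),
                             n_permutations = 1000L, seed = 1L,
                             swap_factor = 10) {
  method <- match.arg(method)
  if (length(focal) == 0L) return(stats::setNames(numeric(0), character(0)))
  nod_tab <- compute_nod_all(net)
  idx <- match(focal, nod_tab$mirna_id)
  if (anyNA(idx)) {
    stop(sprintf("focal miRNA(s) absent from the network: %s",
                 paste(focal[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  obs <- nod_tab$nod[idx]

  if (method == "empirical_tail") {
    m_total <- nrow(nod_tab)
    p <- vapply(obs, function(x) (1 + sum(nod_tab$nod >= x)) / (1 + m_total),
                numeric(1))
    return(stats::setNames(p, focal))
  }

  mirnas <- nod_tab$mirna_id
  genes <- network_genes(net)
  m_idx <- match(net$edges$mirna, mirnas) - 1L
  g_idx <- match(net$edges$gene, genes) - 1L
  set.seed(seed)
  perm <- nod_permutation_counts(m_idx, g_idx, length(mirnas), length(genes),
                                 match(focal, mirnas) - 1L,
                                 as.integer(n_permutations), swap_factor)
  exceed <- colSums(sweep(perm, 2L, obs, `>=`))
  stats::setNames((1 + exceed) / (1 + n_permutations), focal)
}

# threshold NOD-scored records into the candidate ordering used throughout:
# nod desc, nod p asc, then ID
select_candidates <- function(records, nod_alpha) {
  ord <- order(-records$nod, records$nod_pvalue, records$mirna_id)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  records$selected <- records$nod_pvalue < nod_alpha & records$nod >= 1L
  records
}

#' Run the full POMA biomarker-prioritization pipeline
#'
#' Composes the four stages: differential-expression selection
#' ([select_de()]), mapping of DE miRNAs onto the regulatory network
#' ([map_de_to_network()]), NOD computation against the FULL network
#' (uniqueness is judged against all network miRNAs, not only the DE
#' subset), and NOD significance ([nod_null_pvalues()]) thresholded at
#' `nod_alpha`. A candidate must therefore be both differentially
#' expressed AND have significantly many exclusive targets.
#'
#' @param expr An `expression_matrix`.
#' @param net A `regulatory_network`.
#' @param config A `poma_config`.
#' @return An object of class `candidate_set`: list with `records` (data
#'   frame: `mirna_id`, `de_p_value`, `log2_fc`, `out_degree`, `nod`,
#'   `nod_pvalue`, `selected`; ordered nod desc, p asc, ID), `selected`
#'   (character vector of candidate IDs), `unmapped`, and `provenance`
#'   (config echo plus stage-by-stage counts).
#' @export
run_poma <- function(expr, net, config = poma_config()) {
  stopifnot(inherits(config, "poma_config"))
  de <- select_de(expr, config$de_p_threshold, config$fc_threshold,
                  config$variant)
  parts <- map_de_to_network(de, net)
  if (length(parts$mapped) == 0L) {
    warning("no selected DE miRNA maps onto the network; empty candidate set",
            call. = FALSE)
    records <- data.frame(mirna_id = character(0), de_p_value = numeric(0),
                          log2_fc = numeric(0), out_degree = integer(0),
                          nod = integer(0), nod_pvalue = numeric(0),
                          selected = logical(0), stringsAsFactors = FALSE)
  } else {
    nod_tab <- compute_nod_all(net)
    i <- match(parts$mapped, nod_tab$mirna_id)
    j <- match(parts$mapped, de$mirna_id)
    pv <- nod_null_pvalues(net, parts$mapped, config$null_method,
                           config$n_permutations, config$seed)
    records <- data.frame(
      mirna_id = parts$mapped,
      de_p_value = de$p_value[j],
      log2_fc = de$log2_fc[j],
      out_degree = nod_tab$out_degree[i],
      nod = nod_tab$nod[i],
      nod_pvalue = unname(pv[parts$mapped]),
      stringsAsFactors = FALSE
    )
    records <- select_candidates(records, config$nod_alpha)
  }
  structure(
    list(records = records,
         selected = records$mirna_id[records$selected],
         unmapped = parts$unmapped,
         provenance = list(
           config = unclass(config),
           counts = list(
             n_mirnas_tested = nrow(de),
             n_de_selected = sum(de$selected),
             n_mapped = length(parts$mapped),
             n_unmapped = length(parts$unmapped),
             n_candidates = sum(records$selected)
           )
         )),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cnt <- x$provenance$counts
  cat(sprintf(
    "POMA candidate set: %d/%d DE miRNAs mapped onto the network, %d candidate biomarker(s)\n",
    cnt$n_mapped, cnt$n_de_selected, cnt$n_candidates))
  if (length(x$selected) > 0L) {
    print(x$records[x$records$selected,
                    c("mirna_id", "de_p_value", "out_degree", "nod", "nod_pvalue")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a candidate set as TSV with a JSON provenance sidecar
#'
#' The TSV mirrors the candidate-table convention (miRNA, DE p-value,
#' number of targets, NOD, NOD p-value); `<path>.provenance.json` records
#' the config and stage counts needed to re-run the selection.
#'
#' @param candidates A `candidate_set`.
#' @param path Output TSV path.
#' @export
write_candidates <- function(candidates, path) {
  r <- candidates$records
  out <- data.frame(mirna_id = r$mirna_id, de_p_value = r$de_p_value,
                    n_targets = r$out_degree, nod = r$nod,
                    nod_p_value = r$nod_pvalue, selected = r$selected,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(candidates$provenance,
                       paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
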