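#' Truth record for a planted-signal benchmark
#'
#' Defines the ground truth of a synthetic benchmark in which only miRNAs
#' that are BOTH differentially expressed AND rich in exclusive targets
#' should be selected. Three disjoint planted groups probe the two axes:
#' `planted_biomarkers` (DE and high NOD — must be recovered),
#' `planted_de_only` (DE but NOD 0 — must be rejected at the NOD stage),
#' and `planted_highnod_only` (high NOD but not DE — must be rejected at
#' the DE stage).
#'
#' @param planted_biomarkers,planted_de_only,planted_highnod_only
#'   Character vectors of miRNA IDs; pairwise disjoint.
#' @param effect_log2 Log2 expression shift planted in responders
#'   (default 2, i.e. a 4-fold change — a strong biomarker-grade signal).
#' @param noise_sigma Gaussian noise SD on the log2 scale (default 0.5,
#'   typical residual spread of normalized arrays).
#' @param unique_targets_per_biomarker Genes reserved exclusively for each
#'   high-NOD planted miRNA (default 8).
#' @param seed Integer seed for all generator randomness.
#' @return A list of class `benchmark_truth`.
#' @export
benchmark_truth <- function(planted_biomarkers, planted_de_only = character(0),
                            planted_highnod_only = character(0),
                            effect_log2 = 2, noise_sigma = 0.5,
                            unique_targets_per_biomarker = 8L, seed = 1L) {
  if (noise_sigma <= 0) stop("noise_sigma must be positive", call. = FALSE)
  groups <- list(planted_biomarkers, planted_de_only, planted_highnod_only)
  all_ids <- unlist(groups)
  if (anyDuplicated(all_ids)) {
    stop("planted groups must be pairwise disjoint", call. = FALSE)
  }
  structure(list(planted_biomarkers = planted_biomarkers,
                 planted_de_only = planted_de_only,
                 planted_highnod_only = planted_highnod_only,
                 effect_log2 = effect_log2, noise_sigma = noise_sigma,
                 unique_targets_per_biomarker = as.integer(unique_targets_per_biomarker),
                 seed = as.integer(seed)),
            class = "benchmark_truth")
}

#' Generate a bipartite regulatory network with planted exclusive targets
#'
#' Background edges are drawn per miRNA with Poisson(`mean_degree`)
#' out-degree from a shared gene pool (so background genes can acquire
#' several regulators). On top of that, every planted biomarker and every
#' high-NOD-only decoy receives `unique_targets_per_biomarker` genes
#' reserved for it alone — background edges never touch reserved genes, so
#' a planted miRNA's NOD is at least its reservation by construction.
#' DE-only decoys are forced to NOD 0: any of their targets left with a
#' single regulator gains a second one from a random background miRNA.
#'
#' @param n_mirna Total number of miRNAs (IDs `mir-s001` ...; planted IDs
#'   in `truth` must be among them or are taken from the head of the
#'   list — pass the IDs returned by [benchmark_mirna_ids()] to be
#'   explicit).
#' @param n_gene Number of genes in the universe (`G0001` ...).
#' @param mean_degree Expected background out-degree per miRNA.
#' @param truth A `benchmark_truth`.
#' @return A `regulatory_network` with source label `"synthetic"`.
#' @export
generate_network <- function(n_mirna, n_gene, mean_degree, truth) {
  stopifnot(inherits(truth, "benchmark_truth"))
  mirnas <- benchmark_mirna_ids(n_mirna)
  planted_all <- c(truth$planted_biomarkers, truth$planted_de_only,
                   truth$planted_highnod_only)
  if (!all(planted_all %in% mirnas)) {
    stop("planted miRNA IDs must be among the generated IDs (see benchmark_mirna_ids)",
         call. = FALSE)
  }
  r <- truth$unique_targets_per_biomarker
  highnod <- c(truth$planted_biomarkers, truth$planted_highnod_only)
  n_reserved <- length(highnod) * r
  if (n_reserved > n_gene) {
    stop(sprintf("reservation infeasible: need n_gene >= %d for %d high-NOD miRNAs x %d reserved genes",
                 n_reserved, length(highnod), r), call. = FALSE)
  }
  genes <- sprintf("G%04d", seq_len(n_gene))
  reserved <- genes[seq_len(n_reserved)]
  pool <- genes[-seq_len(n_reserved)]
  if (length(pool) == 0L) stop("no background gene pool left after reservation",
                               call. = FALSE)
  set.seed(truth$seed)
  # background layer
  deg <- stats::rpois(n_mirna, mean_degree)
  deg <- pmin(deg, length(pool))
  em <- rep(mirnas, deg)
  eg <- unlist(lapply(deg, function(d) sample(pool, d)))
  # reserved exclusive layer
  for (i in seq_along(highnod)) {
    em <- c(em, rep(highnod[i], r))
    eg <- c(eg, reserved[((i - 1L) * r + 1L):(i * r)])
  }
  # force DE-only decoys to NOD 0: give each of their singly-regulated
  # targets a second regulator from the background miRNAs
  if (length(truth$planted_de_only) > 0L) {
    background <- setdiff(mirnas, planted_all)
    indeg <- table(eg)
    de_only_edges <- which(em %in% truth$planted_de_only)
    lone <- de_only_edges[indeg[eg[de_only_edges]] == 1L]
    if (length(lone) > 0L && length(background) > 0L) {
      em <- c(em, sample(background, length(lone), replace = TRUE))
      eg <- c(eg, eg[lone])
    }
  }
  regulatory_network(em, eg, "synthetic")
}

#' Canonical benchmark miRNA identifiers
#'
#' @param n_mirna Number of IDs.
#' @return Character vector `mir-s001`, `mir-s002`, ...
#' @export
benchmark_mirna_ids <- function(n_mirna) sprintf("mir-s%03d", seq_len(n_mirna))

#' Generate a two-group log2 expression matrix with planted DE signal
#'
#' Per-miRNA baseline abundance is drawn once from Uniform(4, 12) (typical
#' normalized log2 array intensities); every sample observes
#' baseline + Gaussian noise. miRNAs planted as DE (biomarkers and
#' DE-only decoys) are shifted by `effect_log2` in the responder group.
#' Group sizes default to a 9 vs 29 responder / non-responder design.
#'
#' @param n_responders,n_nonresponders Group sizes (defaults 9 and 29).
#' @param mirnas Character vector of miRNA row IDs (must contain all
#'   planted DE miRNAs).
#' @param truth A `benchmark_truth`.
#' @return An `expression_matrix` on the log2 scale.
#' @export
generate_expression <- function(n_responders = 9L, n_nonresponders = 29L,
                                mirnas, truth) {
  stopifnot(inherits(truth, "benchmark_truth"))
  planted_de <- c(truth$planted_biomarkers, truth$planted_de_only)
  if (!all(planted_de %in% mirnas)) {
    stop("planted DE miRNAs must be among the supplied miRNA IDs", call. = FALSE)
  }
  n_m <- length(mirnas)
  n_s <- n_responders + n_nonresponders
  set.seed(truth$seed + 1L)
  baseline <- stats::runif(n_m, 4, 12)
  values <- baseline +
    matrix(stats::rnorm(n_m * n_s, sd = truth$noise_sigma), n_m, n_s)
  shift_rows <- mirnas %in% planted_de
  values[shift_rows, seq_len(n_responders)] <-
    values[shift_rows, seq_len(n_responders), drop = FALSE] + truth$effect_log2
  samples <- c(sprintf("R%02d", seq_len(n_responders)),
               sprintf("N%02d", seq_len(n_nonresponders)))
  dimnames(values) <- list(mirnas, samples)
  groups <- stats::setNames(
    rep(c("responder", "non_responder"), c(n_responders, n_nonresponders)),
    samples)
  expression_matrix(values, groups, scale = "log2")
}

#' Run the standard planted-signal benchmark end to end
#'
#' The reference conditions used throughout the package's validation:
#' 100 miRNAs, 1000 genes, background mean degree 20, a 9 vs 29 sample
#' design, 5 planted biomarkers plus 3 DE-only and 3 high-NOD-only decoys,
#' a 2.0 log2 effect with sigma 0.5, and 8 reserved exclusive targets per
#' high-NOD miRNA. The NOD null is the degree-preserving rewiring
#' permutation: the planted signal is exclusivity beyond degree, which the
#' network-rank (empirical tail) null cannot resolve for a multi-member
#' planted cohort (see the methods vignette).
#'
#' @param seed Integer seed; drives network, expression and permutations.
#' @param n_mirna,n_gene,mean_degree Network dimensions.
#' @param n_biomarkers,n_de_only,n_highnod_only Planted group sizes.
#' @param n_responders,n_nonresponders Expression group sizes.
#' @param effect_log2,noise_sigma,unique_targets_per_biomarker Signal
#'   parameters, see [benchmark_truth()].
#' @param n_permutations Rewiring permutations for the NOD null.
#' @return List: `truth`, `net`, `expr`, `candidates` (a `candidate_set`),
#'   and `eval` with `sensitivity` (recovered fraction of planted
#'   biomarkers), `false_discoveries` (selected non-biomarkers),
#'   `false_discovery_prop`, and `exact_recovery` (selected set equals the
#'   planted biomarker set).
#' @export
poma_benchmark <- function(seed = 1L, n_mirna = 100L, n_gene = 1000L,
                           mean_degree = 20, n_biomarkers = 5L,
                           n_de_only = 3L, n_highnod_only = 3L,
                           n_responders = 9L, n_nonresponders = 29L,
                           effect_log2 = 2, noise_sigma = 0.5,
                           unique_targets_per_biomarker = 8L,
                           n_permutations = 1000L) {
  mirnas <- benchmark_mirna_ids(n_mirna)
  idx <- seq_len(n_biomarkers + n_de_only + n_highnod_only)
  stopifnot(length(idx) <= n_mirna)
  truth <- benchmark_truth(
    planted_biomarkers = mirnas[seq_len(n_biomarkers)],
    planted_de_only = mirnas[n_biomarkers + seq_len(n_de_only)],
    planted_highnod_only = mirnas[n_biomarkers + n_de_only + seq_len(n_highnod_only)],
    effect_log2 = effect_log2, noise_sigma = noise_sigma,
    unique_targets_per_biomarker = unique_targets_per_biomarker,
    seed = as.integer(seed))
  net <- generate_network(n_mirna, n_gene, mean_degree, truth)
  expr <- generate_expression(n_responders, n_nonresponders, mirnas, truth)
  config <- poma_config(null_method = "rewire_permutation",
                        n_permutations = n_permutations,
                        seed = as.integer(seed) + 2L)
  candidates <- run_poma(expr, net, config)
  sel <- candidates$selected
  tp <- intersect(sel, truth$planted_biomarkers)
  fd <- setdiff(sel, truth$planted_biomarkers)
  list(truth = truth, net = net, expr = expr, candidates = candidates,
       eval = list(
         sensitivity = length(tp) / length(truth$planted_biomarkers),
         false_discoveries = fd,
         false_discovery_prop = if (length(sel) == 0L) 0
                                else length(fd) / length(sel),
         exact_recovery = setequal(sel, truth$planted_biomarkers)
       ))
}

#' Write a full synthetic fixture bundle to a directory
#'
#' Emits `edges.tsv`, `expression.tsv`, `groups.tsv` and `truth.json` so
#' the pipeline can be exercised from files alone.
#'
#' @param dir Output directory (created if needed).
#' @param net A `regulatory_network`.
#' @param expr An `expression_matrix`.
#' @param truth A `benchmark_truth`.
#' @return The directory path, invisibly.
#' @export
write_benchmark_bundle <- function(dir, net, expr, truth) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(net, file.path(dir, "edges.tsv"))
  mat <- data.frame(mirna_id = rownames(expr$values), expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(mat, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  grp <- data.frame(sample_id = names(expr$groups),
                    group = unname(expr$groups), stringsAsFactors = FALSE)
  utils::write.table(grp, file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
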