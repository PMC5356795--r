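test_that("map_de_to_network partitions selected DE miRNAs by network membership", {
  net <- regulatory_network("a", "G1")
  parts <- map_de_to_network(c("a", "b"), net)
  expect_identical(parts$mapped, "a")
  expect_identical(parts$unmapped, "b")
  empty <- map_de_to_network(character(0), net)
  expect_length(empty$mapped, 0)
  expect_length(empty$unmapped, 0)
  # random fixture: partition covers the DE set, disjointly
  e <- random_edges(10, 30, 0.1, seed = 3)
  net2 <- regulatory_network(e$m, e$g)
  de_set <- c(sample(unique(e$m), 4), "mqq", "mzz")
  parts2 <- map_de_to_network(de_set, net2)
  expect_setequal(c(parts2$mapped, parts2$unmapped), de_set)
  expect_length(intersect(parts2$mapped, parts2$unmapped), 0)
})

test_that("empirical-tail NOD p-values follow the rank formula", {
  # one miRNA with the strictly largest NOD among M: p = (1+1)/(1+M)
  net <- regulatory_network(
    c(rep("mtop", 5), "m2", "m2", "m3"),
    c(sprintf("U%d", 1:5), "S1", "S2", "S1"))
  nod <- compute_nod_all(net)
  expect_equal(nod$nod[nod$mirna_id == "mtop"], 5L)
  p <- nod_null_pvalues(net, "mtop", "empirical_tail")
  expect_equal(unname(p), 2 / 4)
  # degenerate: all miRNAs with identical NOD get p = 1
  flat <- regulatory_network(c("m1", "m2", "m3"), c("A", "B", "C"))
  pf <- nod_null_pvalues(flat, c("m1", "m2", "m3"), "empirical_tail")
  expect_equal(unname(pf), rep(1, 3))
  expect_error(nod_null_pvalues(flat, "nope", "empirical_tail"), "nope")
  # within one run, higher NOD never has the larger p
  e <- random_edges(15, 60, 0.1, seed = 9)
  net2 <- regulatory_network(e$m, e$g)
  nod2 <- compute_nod_all(net2)
  p2 <- nod_null_pvalues(net2, nod2$mirna_id, "empirical_tail")
  ord <- order(nod2$nod)
  expect_false(is.unsorted(rev(p2[nod2$mirna_id[ord]])))
})

test_that("rewiring p-values are seed-reproducible and Monte-Carlo consistent across seeds", {
  set.seed(5)
  e <- random_edges(5, 12, 0.35, seed = 5)
  net <- regulatory_network(e$m, e$g)
  focal <- network_mirnas(net)
  p1 <- nod_null_pvalues(net, focal, "rewire_permutation",
                         n_permutations = 2000, seed = 101)
  p1_again <- nod_null_pvalues(net, focal, "rewire_permutation",
                               n_permutations = 2000, seed = 101)
  expect_identical(p1, p1_again)
  p2 <- nod_null_pvalues(net, focal, "rewire_permutation",
                         n_permutations = 2000, seed = 202)
  # two independent estimates of the same tail probability: difference
  # bounded by the 99% Monte-Carlo band of the seed-to-seed difference
  pbar <- (p1 + p2) / 2
  band <- 2.576 * sqrt(2 * pbar * (1 - pbar) / 2000) + 2 / 2001
  expect_true(all(abs(p1 - p2) <= band))
  # +1 smoothing keeps p off 0 and within (0, 1]
  expect_true(all(p1 > 0 & p1 <= 1))
})

test_that("candidate selection is monotone in alpha and deterministic given a seed", {
  bench <- poma_benchmark(seed = 7, n_permutations = 200)
  records <- bench$candidates$records
  sel_at <- function(alpha) {
    r <- records
    r$selected <- r$nod_pvalue < alpha & r$nod >= 1
    r$mirna_id[r$selected]
  }
  alphas <- c(0.001, 0.01, 0.05, 0.2)
  for (i in seq_len(length(alphas) - 1)) {
    expect_true(all(sel_at(alphas[i]) %in% sel_at(alphas[i + 1])))
  }
  # candidate ordering: nod desc, then p asc, then ID
  expect_true(all(diff(records$nod) <= 0))
  # byte-identical rerun under the same seed
  bench2 <- poma_benchmark(seed = 7, n_permutations = 200)
  expect_identical(bench2$candidates$records, records)
  expect_identical(bench2$candidates$selected, bench$candidates$selected)
})

test_that("run_poma composes the stages with full provenance, and alpha 0 empties the selection", {
  bench <- poma_benchmark(seed = 12, n_permutations = 200)
  cand <- bench$candidates
  cnt <- cand$provenance$counts
  expect_equal(cnt$n_mirnas_tested, 100L)
  expect_equal(cnt$n_mapped + cnt$n_unmapped, cnt$n_de_selected)
  expect_equal(cnt$n_candidates, length(cand$selected))
  expect_true(all(cand$records$nod[cand$records$selected] >= 1))

  cfg0 <- poma_config(nod_alpha = 0, null_method = "rewire_permutation",
                      n_permutations = 200, seed = 1)
  cand0 <- run_poma(bench$expr, bench$net, cfg0)
  expect_length(cand0$selected, 0)

  # no DE miRNA on the network: empty set with a warning, not an error
  offnet <- regulatory_network("mir-elsewhere", "G1")
  expect_warning(res <- run_poma(bench$expr, offnet, cfg0), "no selected DE")
  expect_length(res$selected, 0)
})

test_that("thresholding the packaged candidate table selects the nine biomarkers", {
  tab <- candidate_biomarker_table()
  selected <- tab$mirna_id[tab$nod_p_value < 0.05 & tab$nod >= 1]
  expect_length(selected, 9)
  expect_true(all(c("mir-198", "mir-765", "mir-513a-5p") %in% selected))
  # printed NOD -> p mapping is monotone, matching the empirical-tail pattern
  ord <- order(-tab$nod)
  expect_false(is.unsorted(tab$nod_p_value[ord]))
})

test_that("candidate writer emits the table plus a provenance sidecar", {
  bench <- poma_benchmark(seed = 3, n_permutations = 200)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(bench$candidates, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(bench$candidates$records))
  expect_named(back, c("mirna_id", "de_p_value", "n_targets", "nod",
                       "nod_p_value", "selected"))
  sidecar <- jsonlite::read_json(paste0(path, ".provenance.json"))
  expect_equal(sidecar$counts$n_candidates,
               length(bench$candidates$selected))
})
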