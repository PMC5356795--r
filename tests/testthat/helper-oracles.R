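# Independent oracles for property tests. These deliberately use naive
# brute-force formulations, not the package's code paths.

# random bipartite edge list (data frame m, g), Bernoulli per pair
random_edges <- function(n_m, n_g, p, seed) {
  set.seed(seed)
  grid <- expand.grid(m = sprintf("m%02d", seq_len(n_m)),
                      g = sprintf("g%03d", seq_len(n_g)),
                      stringsAsFactors = FALSE)
  grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
}

# per-gene brute force: a miRNA's NOD counts its targets whose regulator
# count, obtained by scanning the full edge list, is exactly 1
brute_nod_oracle <- function(edges) {
  edges <- unique(edges[c("m", "g")])
  mirnas <- sort(unique(edges$m))
  nod <- vapply(mirnas, function(mm) {
    targets <- edges$g[edges$m == mm]
    sum(vapply(targets, function(gg) sum(edges$g == gg), numeric(1)) == 1)
  }, numeric(1))
  data.frame(mirna_id = mirnas, nod = as.integer(nod),
             stringsAsFactors = FALSE)
}

# classical pooled-variance two-sample t, textbook formula
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(tstat), df = na + nb - 2)
}

# exhaustive hypergeometric upper tail: fraction of all query-size draws
# from the universe whose overlap with the set reaches the observed one
hyper_enum_oracle <- function(universe, set_genes, query_size, observed_overlap) {
  draws <- utils::combn(universe, query_size)
  overlaps <- apply(draws, 2, function(d) length(intersect(d, set_genes)))
  mean(overlaps >= observed_overlap)
}

# tiny expression fixture writer used by the I/O tests
write_expr_fixture <- function(dir, values, groups) {
  expr_path <- file.path(dir, "expr.tsv")
  grp_path <- file.path(dir, "groups.tsv")
  df <- data.frame(mirna_id = rownames(values), values, check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(groups), group = unname(groups)),
                     grp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(expr = expr_path, groups = grp_path)
}
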