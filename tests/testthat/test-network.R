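test_that("miRNA ID normalization lowercases, strips the species prefix, and is idempotent", {
  expect_identical(normalize_mirna_id("hsa-miR-765"), "mir-765")
  expect_identical(normalize_mirna_id("mir-765"), "mir-765")
  expect_identical(normalize_mirna_id(normalize_mirna_id("hsa-miR-630")),
                   normalize_mirna_id("hsa-miR-630"))
  # arm and letter suffixes survive
  expect_identical(normalize_mirna_id("hsa-miR-513a-5p"), "mir-513a-5p")
  expect_error(normalize_mirna_id(""), "non-empty")
})

test_that("the alias table reconciles reported names with official ones", {
  alias <- mirna_alias_table()
  expect_identical(normalize_mirna_id("miR-630", alias), "mir-630")
  expect_identical(normalize_mirna_id("miR-196b", alias), "mir-196b-5p")
  # alias output is a fixed point of normalization
  expect_identical(normalize_mirna_id("mir-196b-5p", alias), "mir-196b-5p")
  # same miRNA written with and without species prefix converges
  expect_identical(normalize_mirna_id("hsa-miR-630", alias),
                   normalize_mirna_id("miR-630", alias))
})

test_that("read_edge_list normalizes, deduplicates, tags provenance, and ignores row order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna\tgene",
               "hsa-miR-630\tabc1",
               "miR-630\tABC1",   # duplicate after normalization
               "miR-765\txyz2"), path)
  net <- read_edge_list(path, "dbA")
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$edges$mirna, c("mir-630", "mir-765"))
  expect_true(all(net$edges$gene %in% c("ABC1", "XYZ2")))
  expect_true(all(vapply(net$edges$sources, identical, logical(1), "dbA")))

  # shuffled rows give the identical network
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna\tgene", "miR-765\txyz2", "miR-630\tABC1",
               "hsa-miR-630\tabc1"), path2)
  net2 <- read_edge_list(path2, "dbA")
  ord <- function(n) n$edges[order(n$edges$mirna, n$edges$gene), c("mirna", "gene")]
  expect_equal(ord(net2), ord(net), ignore_attr = TRUE)
})

test_that("read_edge_list flags missing columns, malformed rows, and empty files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "x\ty"), path)
  expect_error(read_edge_list(path, "db",
                              dialect = list(mirna_col = "mirna", gene_col = "b")),
               "mirna")
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna\tgene", "miR-1\t", "miR-2\tG1"), path3)
  expect_warning(net <- read_edge_list(path3, "db"), "malformed")
  expect_equal(nrow(net$edges), 1L)
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_warning(net0 <- read_edge_list(empty, "db"), "empty")
  expect_equal(nrow(net0$edges), 0L)
})

test_that("edge counts from random files match a brute-force set oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- sprintf("miR-%d", sample(1:6, 10, replace = TRUE))
    g <- sprintf("G%d", sample(1:8, 10, replace = TRUE))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("mirna\tgene", paste(m, g, sep = "\t")), path)
    net <- read_edge_list(path, "db")
    oracle <- length(unique(paste(tolower(m), toupper(g))))
    expect_equal(nrow(net$edges), oracle)
  }
})

test_that("merge_networks takes the union with concatenated, deduplicated provenance", {
  a <- regulatory_network("x", "G1", "dbA")
  b <- regulatory_network(c("x", "y"), c("G1", "G2"), "dbB")
  m <- merge_networks(list(a, b))
  expect_equal(nrow(m$edges), 2L)
  shared <- m$edges$sources[[which(m$edges$mirna == "x")]]
  expect_setequal(shared, c("dbA", "dbB"))
  # idempotence
  aa <- merge_networks(list(a, a))
  expect_equal(nrow(aa$edges), 1L)
  expect_identical(aa$edges$sources[[1L]], "dbA")
  # empty input
  expect_equal(nrow(merge_networks(list())$edges), 0L)
})

test_that("merge union size matches a brute-force set union, commutatively", {
  nets <- lapply(1:3, function(s) {
    e <- random_edges(8, 15, 0.18, seed = s)
    regulatory_network(e$m, e$g, sprintf("db%d", s))
  })
  merged <- merge_networks(nets)
  all_pairs <- unique(do.call(rbind, lapply(nets, function(n) n$edges[c("mirna", "gene")])))
  expect_equal(nrow(merged$edges), nrow(all_pairs))
  rev_merged <- merge_networks(rev(nets))
  ord <- function(n) n$edges[order(n$edges$mirna, n$edges$gene), c("mirna", "gene")]
  expect_equal(ord(rev_merged), ord(merged), ignore_attr = TRUE)
})

test_that("compute_nod handles sole-regulator and fully-shared cases", {
  solo <- regulatory_network(rep("m1", 3), c("G1", "G2", "G3"))
  rec <- compute_nod(solo, "m1")
  expect_equal(rec$nod, 3L)
  expect_equal(rec$out_degree, 3L)
  expect_setequal(rec$unique_targets, c("G1", "G2", "G3"))

  shared <- regulatory_network(c("m1", "m1", "m2", "m2"),
                               c("G1", "G2", "G1", "G2"))
  expect_equal(compute_nod(shared, "m1")$nod, 0L)
  expect_equal(compute_nod(shared, "m2")$nod, 0L)
  expect_error(compute_nod(shared, "m3"), "m3")
})

test_that("compute_nod_all matches the per-gene brute-force oracle on random graphs", {
  for (seed in 1:30) {
    set.seed(seed + 1000)
    e <- random_edges(sample(5:40, 1), sample(20:200, 1),
                      stats::runif(1, 0.02, 0.2), seed = seed)
    if (nrow(e) == 0L) next
    net <- regulatory_network(e$m, e$g)
    got <- compute_nod_all(net)
    oracle <- brute_nod_oracle(e)
    expect_equal(got$mirna_id, oracle$mirna_id)
    expect_equal(got$nod, oracle$nod)
    # conservation: sum of NOD equals the number of in-degree-1 genes,
    # sum of out-degrees equals the edge count
    indeg <- table(net$edges$gene)
    expect_equal(sum(got$nod), sum(indeg == 1))
    expect_equal(sum(got$out_degree), nrow(net$edges))
    # per-record consistency with the single-miRNA path on a few rows
    for (mm in utils::head(got$mirna_id, 3)) {
      expect_equal(compute_nod(net, mm)$nod, got$nod[got$mirna_id == mm])
    }
  }
})

test_that("removing a competitor never decreases NOD; adding one never increases it", {
  e <- random_edges(10, 40, 0.12, seed = 7)
  net <- regulatory_network(e$m, e$g)
  nod0 <- compute_nod_all(net)
  victim <- nod0$mirna_id[1L]
  for (other in setdiff(nod0$mirna_id, victim)) {
    keep <- net$edges$mirna != other
    reduced <- regulatory_network(net$edges$mirna[keep], net$edges$gene[keep])
    expect_gte(compute_nod(reduced, victim)$nod,
               nod0$nod[nod0$mirna_id == victim])
  }
  # merge monotonicity: in the union with another network (victim's own
  # edges untouched), victim's NOD can only drop
  extra <- regulatory_network(c("mzz", "mzz"), sample(unique(e$g), 2), "dbX")
  merged <- merge_networks(list(net, extra))
  expect_lte(compute_nod(merged, victim)$nod, nod0$nod[nod0$mirna_id == victim])
})

test_that("network writers round-trip edges and mark node kinds", {
  net <- regulatory_network(c("m1", "m1", "m2"), c("G1", "G2", "G1"), "db")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, tsv)
  back <- read_edge_list(tsv, "reread")
  expect_equal(nrow(back$edges), 3L)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network_sif(net, sif)
  expect_equal(length(readLines(sif)), 3L)
  g <- as_network_igraph(net)
  kinds <- igraph::V(g)$kind
  expect_setequal(kinds[igraph::V(g)$name %in% c("m1", "m2")], "mirna")
  expect_setequal(kinds[igraph::V(g)$name %in% c("G1", "G2")], "gene")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  expect_true(any(grepl("graphml", readLines(gml, n = 5))))
})
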