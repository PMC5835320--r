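test_that("curated functional groups classify known determinants", {
  cls <- classify_functional_groups(c("ID1", "PTPRC", "NOT_A_GENE", "id1"))
  expect_equal(unname(cls["ID1"]), "apoptosis")
  expect_equal(unname(cls["PTPRC"]), "cytoskeleton")
  expect_equal(unname(cls["NOT_A_GENE"]), "unclassified")
  # case-insensitive
  expect_equal(unname(cls["id1"]), "apoptosis")
})

test_that("the packaged determinant table is complete and one-group-per-entry", {
  tab <- functional_group_table()
  expect_false(anyDuplicated(tab$symbol) > 0)
  groups <- c("oxidative stress response", "drug transport", "DNA repair",
              "cell cycle/proliferation", "tumor suppressors/oncogenes",
              "signal transduction", "metabolic pathways", "cytoskeleton",
              "apoptosis")
  expect_setequal(unique(tab$group), groups)
  # every published determinant label is present
  expected_labels <- c(
    "GSH", "SOD (Cu/Zn)", "NXN", "TXNRD1", "BACH2",
    "gamma-glutamyltransferase", "HO-1", "HIF-1alpha", "GST-pi",
    "ABCC1 (MRP1)", "ABCC2 (MRP2)", "ABCC4 (MRP4)", "ASAN1",
    "SMC2L1", "hMSH2",
    "ARHGAPAP19", "CDKN2D", "PRKACA", "TFDP2", "ZNF151", "p21WAF/CIP",
    "BTBD2", "IGFBP1", "CCND1", "AURKB",
    "RBBP4", "CHMP1A", "GPRC5A", "PML/RARAalpha", "p53", "EGFR", "MYC",
    "CAMK4", "PPAP2C", "PKB3", "AP-1 (Fos/Jun)", "DDEF2", "SDC1",
    "SH2BP3", "STMN1", "TJP1", "PI3K", "PKC", "AKT", "NFKB1",
    "ME1", "COAS4", "ALDH3A2", "ALDH3A1",
    "PTPRC", "ABLIM1", "EPB41L1", "PLS1", "ACAA2", "ARHGEF7", "KRT8",
    "MYL3",
    "ID1", "GRB7", "PIGPC1", "Bcl2", "Noxa", "Mcl-1")
  expect_setequal(tab$label, expected_labels)
})

test_that("a fully overlapping set gives the exact combinatorial p-value", {
  universe <- sprintf("U%02d", 1:20)
  sets <- gene_set_collection(list(
    FULL = list(description = "d", genes = universe[1:5]),
    MISS = list(description = "d", genes = universe[16:18])))
  res <- ora_fisher(universe[1:5], sets, universe)
  full <- res[res$set_name == "FULL", ]
  expect_equal(full$overlap, 5L)
  expect_equal(full$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(full$passes_cutoff)
  miss <- res[res$set_name == "MISS", ]
  expect_equal(miss$overlap, 0L)
  expect_equal(miss$p, 1)
  expect_false(miss$passes_cutoff)
})

test_that("the 1.3 cutoff is inclusive", {
  # construct p exactly at the cutoff boundary via direct flag arithmetic
  res <- data.frame(neg_log10_p = c(1.30, 1.29, 1.31))
  flags <- res$neg_log10_p >= 1.3 - 1e-12
  expect_equal(flags, c(TRUE, FALSE, TRUE))

  universe <- sprintf("U%d", 1:40)
  sets <- gene_set_collection(list(S = list(description = "", genes = universe[1:10])))
  out <- ora_fisher(universe[1:12], sets, universe, cutoff_neg_log10_p = 1.3)
  expect_identical(out$passes_cutoff, out$neg_log10_p >= 1.3 - 1e-12)
})

test_that("hypergeometric tails match an explicit summation oracle", {
  set.seed(13)
  for (i in 1:20) {
    N <- sample(20:200, 1)
    K <- sample(3:(N %/% 2), 1)
    n <- sample(3:(N %/% 2), 1)
    universe <- sprintf("g%03d", 1:N)
    set_genes <- sample(universe, K)
    query <- sample(universe, n)
    sets <- gene_set_collection(list(S = list(description = "", genes = set_genes)))
    res <- ora_fisher(query, sets, universe)
    k <- length(intersect(set_genes, query))
    expect_equal(res$overlap, k)
    expect_equal(res$p, hyper_tail_oracle(k, K, N, n),
                 tolerance = 1e-9)
  }
})

test_that("larger overlap at fixed margins never increases the p-value", {
  N <- 100; K <- 20; n <- 15
  ps <- vapply(0:min(K, n), function(k)
    hyper_tail_oracle(k, K, N, n), numeric(1))
  impl <- vapply(0:min(K, n), function(k)
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE), numeric(1))
  expect_true(all(diff(impl) <= 1e-15))
  expect_equal(impl, ps, tolerance = 1e-9)
})

test_that("query genes outside the universe are dropped with a warning", {
  universe <- sprintf("u%d", 1:10)
  sets <- gene_set_collection(list(S = list(description = "", genes = universe[1:4])))
  expect_warning(res <- ora_fisher(c(universe[1:3], "ALIEN"), sets, universe),
                 "outside the universe")
  expect_equal(res$query_size, 3L)
  expect_error(ora_fisher(character(0), sets, universe), "empty query")
})

test_that("network assembly labels nodes and enforces edge hygiene", {
  genes <- c("ID1", "PTPRC", "PRKACA")
  net <- assemble_network(genes, edges = NULL)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(igraph::vcount(net$graph), 3)
  expect_equal(igraph::ecount(net$graph), 0)
  expect_equal(net$nodes$group[net$nodes$id == "ID1"], "apoptosis")

  edges <- data.frame(a = c("ID1", "ID1", "GHOST"),
                      b = c("PTPRC", "ID1", "PRKACA"),
                      type = c("direct", "indirect", "direct"),
                      provenance = "curated")
  expect_warning(expect_warning(net2 <- assemble_network(genes, edges = edges),
                                "self-loop"), "outside the gene list")
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$type, "direct")

  bad <- data.frame(a = "ID1", b = "PTPRC", type = "sideways",
                    provenance = "x")
  expect_error(assemble_network(genes, edges = bad), "direct")

  tsv <- tempfile(fileext = ".tsv")
  gml <- tempfile(fileext = ".graphml")
  write_network(net2, tsv, "tsv")
  write_network(net2, gml, "graphml")
  expect_equal(utils::read.table(tsv, header = TRUE, sep = "\t")$a, "ID1")
  expect_gt(file.info(gml)$size, 0)
})
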