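test_that("signature standardization z-scores every gene row", {
  set.seed(3)
  expr <- make_expr(matrix(rnorm(40 * 58, mean = 7, sd = 2), 40, 58))
  z <- standardize_signature_matrix(expr, rownames(expr))
  expect_identical(dim(z), c(40L, 58L))
  expect_equal(unname(rowMeans(z)), rep(0, 40), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 40), tolerance = 1e-12)

  flat <- make_expr(rbind(rnorm(6), rep(2, 6)), genes = c("G1", "FLAT"))
  expect_warning(z2 <- standardize_signature_matrix(flat, c("G1", "FLAT")),
                 "zero-variance")
  expect_equal(unname(unclass(z2)["FLAT", ]), rep(0, 6))

  expect_error(standardize_signature_matrix(expr, c("G1", "NOPE")), "NOPE")
})

test_that("Ward merges match the minimal-cost oracle on 1-D quartet", {
  m <- make_expr(matrix(c(0, 0.1, 10, 10.1), nrow = 1),
                 genes = "g", lines = c("a", "b", "c", "d"))
  hc <- ward_cluster(m, "lines")
  # first two merges pair {a,b} and {c,d} at Ward cost 0.1^2
  first_two <- list(sort(hc$merge[1, ]), sort(hc$merge[2, ]))
  expect_true(all(c(-1, -2) %in% unlist(first_two)))
  expect_setequal(unlist(first_two), c(-1, -2, -3, -4))
  expect_equal(hc$height[1:2], c(0.01, 0.01), tolerance = 1e-12)
  expect_true(all(diff(hc$height) >= -1e-12))

  cl <- cut_tree(hc, 2)
  expect_equal(partition_key(cl),
               partition_key(c(a = 1, b = 1, c = 2, d = 2)))
})

test_that("Ward agrees with greedy sum-of-squares agglomeration on random instances", {
  set.seed(12)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    rownames(x) <- letters[seq_len(n)]
    hc <- ward_cluster(t(x), "lines")
    oracle <- ward_oracle(x)
    expect_equal(hc$height, oracle$costs, tolerance = 1e-9)
    for (k in seq_len(n - 1)) {
      cl <- cut_tree(hc, k)
      ocl <- integer(n); names(ocl) <- rownames(x)
      opart <- oracle$partitions[[n - k]]
      for (gi in seq_along(opart)) ocl[opart[[gi]]] <- gi
      expect_equal(partition_key(cl), partition_key(ocl))
    }
  }
})

test_that("identical objects merge first at height zero", {
  m <- make_expr(cbind(c(1, 1), c(1, 1), c(5, 5)),
                 lines = c("x", "y", "z"))
  hc <- ward_cluster(m, "lines")
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
  expect_equal(hc$height[1], 0)
})

test_that("tree cuts cover the degenerate k values and relabel by leaf order", {
  set.seed(4)
  m <- make_expr(matrix(rnorm(30), 3, 10))
  hc <- ward_cluster(m, "lines")
  expect_equal(as.integer(cut_tree(hc, 1)), rep(1L, 10))
  expect_equal(sort(as.integer(cut_tree(hc, 10))), 1:10)
  cl <- cut_tree(hc, 4)
  # labels contiguous 1..k, ordered by first appearance in leaf order
  expect_setequal(unique(unclass(cl)), 1:4)
  leaf_first <- unclass(cl)[hc$labels[hc$order]]
  expect_equal(unique(leaf_first), 1:4)
  expect_error(cut_tree(hc, 11), "between 1 and")
  expect_error(cut_tree(hc, 0), "between 1 and")
})

test_that("object order only permutes labels, never the partition", {
  set.seed(9)
  vals <- matrix(rnorm(5 * 12), 5, 12)
  expr <- make_expr(vals)
  cl1 <- cut_tree(ward_cluster(expr, "lines"), 3)
  perm <- sample(12)
  expr2 <- expression_matrix(vals[, perm], rownames(expr),
                             colnames(expr)[perm])
  cl2 <- cut_tree(ward_cluster(expr2, "lines"), 3)
  expect_equal(partition_key(cl1), partition_key(cl2))
})

test_that("well-separated groups are recovered exactly at k = 2", {
  for (s in 1:20) {
    set.seed(s)
    n1 <- 6; n2 <- 7
    x <- cbind(matrix(rnorm(4 * n1, 0, 0.3), 4),
               matrix(rnorm(4 * n2, 8, 0.3), 4))
    expr <- make_expr(x, lines = sprintf("L%d", 1:(n1 + n2)))
    cl <- cut_tree(ward_cluster(expr, "lines"), 2)
    truth <- setNames(rep(1:2, c(n1, n2)), colnames(expr))
    expect_equal(partition_key(cl), partition_key(truth))
  }
})

test_that("clustered image maps and newick exports are written", {
  set.seed(2)
  expr <- make_expr(matrix(rnorm(20 * 12), 20, 12))
  rd <- ward_cluster(expr, "genes")
  cd <- ward_cluster(expr, "lines")
  ann <- setNames(rep(c("sensitive", "resistant"), 6), colnames(expr))
  path <- tempfile(fileext = ".png")
  render_cim(expr, rd, cd, ann, path)
  expect_true(file.exists(path))
  expect_gt(file.info(path)$size, 0)
  expect_error(render_cim(expr, cd, cd, NULL, tempfile(fileext = ".png")),
               "row dendrogram")

  nwk <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cd, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, colnames(expr))
})
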