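test_that("pca embedding is deterministic and captures collinear geometry", {
  set.seed(5)
  # genes lying on a line in unit space: one component carries all variance
  d <- rnorm(6)
  X <- rbind(2 + 1.0 * d, -1 + 2.5 * d, 4 - 1.5 * d, 0.5 + 0.2 * d)
  e <- fx_expr(X)
  emb <- embed_genes(e, e$gene_ids, "pca", dims = 2)
  expect_lt(max(abs(emb[, 2])), 1e-8)
  expect_gt(stats::sd(emb[, 1]), 0)
  emb2 <- embed_genes(e, e$gene_ids, "pca", dims = 2)
  expect_identical(emb, emb2)
  expect_error(embed_genes(e, e$gene_ids, "pca", dims = 1), "config error")
  expect_error(embed_genes(e, e$gene_ids[1:2], "pca", dims = 2),
               "config error")
  expect_error(embed_genes(e, e$gene_ids, "umap"), "config error")
})

test_that("pca distances agree with a brute-force eigendecomposition", {
  set.seed(6)
  X <- matrix(rnorm(8 * 5), 8, 5)
  e <- fx_expr(X)
  emb <- embed_genes(e, e$gene_ids, "pca", dims = 4)
  # oracle: z-score rows, centre columns, project on eigenvectors of
  # the unit-space scatter matrix
  Z <- t(scale(t(X)))
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Zc), symmetric = TRUE)
  proj <- Zc %*% ev$vectors[, 1:4]
  expect_equal(as.matrix(stats::dist(emb)), as.matrix(stats::dist(proj)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("kNN adjacency follows distances with lexicographic tie-breaks", {
  emb <- matrix(c(0, 1, 3), ncol = 1, dimnames = list(c("a", "b", "c")))
  adj <- knn_adjacency(emb, k = 1)$adj
  expect_equal(adj["a", "b"], 1L)  # mutual nearest
  expect_equal(adj["b", "c"], 1L)  # c's nearest is b, kept by OR
  expect_equal(adj["a", "c"], 0L)
  expect_true(all(adj == t(adj)))
  expect_equal(unname(diag(adj)), rep(0L, 3))
  # saturation: k = n - 1 gives the complete graph
  set.seed(7)
  emb5 <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("g", 1:5)))
  adj5 <- knn_adjacency(emb5, k = 4)$adj
  expect_equal(sum(adj5), 5 * 4)
  # duplicate coordinates: lexicographically smallest id wins the tie
  embd <- matrix(0, 3, 2, dimnames = list(c("g2", "g1", "g3")))
  adjd <- knn_adjacency(embd, k = 1)$adj
  expect_equal(adjd["g2", "g1"], 1L)
  expect_equal(adjd["g3", "g1"], 1L)
  expect_equal(adjd["g2", "g3"], 0L)
  expect_error(knn_adjacency(emb, k = 3), "config error")
})

test_that("fusion is the elementwise OR of the modality adjacencies", {
  mk <- function(m) structure(list(genes = rownames(m), adj = m,
                                   modality = "bulk"),
                              class = "modality_adjacency")
  ids <- c("x", "y")
  for (sc_bit in 0:1) for (bk_bit in 0:1) {
    a <- matrix(c(0L, sc_bit, sc_bit, 0L), 2, dimnames = list(ids, ids))
    b <- matrix(c(0L, bk_bit, bk_bit, 0L), 2, dimnames = list(ids, ids))
    f <- fuse_adjacency(mk(a), mk(b))
    expect_equal(f$adj["x", "y"], as.integer(sc_bit | bk_bit))
  }
  # random pairs: OR, symmetry, zero diagonal, monotonicity
  set.seed(8)
  for (r in 1:20) {
    n <- sample(3:10, 1)
    ids <- paste0("g", 1:n)
    rnd <- function() {
      m <- matrix(rbinom(n * n, 1, 0.4), n)
      m <- 1L * ((m + t(m)) > 0); diag(m) <- 0L
      dimnames(m) <- list(ids, ids); m
    }
    a <- rnd(); b <- rnd()
    f <- fuse_adjacency(mk(a), mk(b))$adj
    expect_equal(f, 1L * ((a | b) & !diag(n)), ignore_attr = TRUE)
    expect_true(all(f == t(f)))
    # adding an edge never removes a fused edge
    a2 <- a
    off <- which(a2 == 0 & upper.tri(a2))
    if (length(off)) {
      i <- arrayInd(off[1], dim(a2))
      a2[i[1], i[2]] <- a2[i[2], i[1]] <- 1L
      f2 <- fuse_adjacency(mk(a2), mk(b))$adj
      expect_true(all(f2 >= f))
    }
  }
  bad <- mk(matrix(0L, 2, 2, dimnames = list(c("p", "q"), c("p", "q"))))
  good <- mk(matrix(0L, 2, 2, dimnames = list(c("x", "y"), c("x", "y"))))
  expect_error(fuse_adjacency(bad, good), "alignment error")
})

test_that("sample graphs are induced subgraphs with 3 features per node", {
  set.seed(9)
  n <- 12
  ids <- sprintf("g%02d", 1:n)
  adj <- matrix(rbinom(n * n, 1, 0.3), n)
  adj <- 1L * ((adj + t(adj)) > 0); diag(adj) <- 0L
  dimnames(adj) <- list(ids, ids)
  fused <- structure(list(genes = ids, adj = adj), class = "fused_adjacency")
  bulk <- expression_matrix(matrix(rnorm(n * 6), n), ids,
                            paste0("s", 1:6), "bulk")
  sc <- expression_matrix(pmax(matrix(rnorm(n * 9), n), 0), ids,
                          paste0("c", 1:9), "single_cell")
  # full induction reproduces the fused adjacency
  g_all <- build_sample_graph("s1", ids, fused, bulk, sc)
  expect_equal(g_all$adj, fused$adj)
  # random subsets: exhaustive induced-submatrix check
  for (r in 1:10) {
    keys <- sample(ids, sample(3:n, 1))
    g <- suppressWarnings(build_sample_graph("s2", keys, fused, bulk, sc))
    for (i in seq_along(keys)) for (j in seq_along(keys)) {
      expect_identical(g$adj[i, j], fused$adj[keys[i], keys[j]])
    }
  }
  # hand-checked 2-node fixture
  two <- names(which(rowSums(adj) > 0))[1]
  partner <- names(which(adj[two, ] == 1))[1]
  g2 <- build_sample_graph("s3", c(two, partner), fused, bulk, sc)
  expect_equal(dim(g2$features), c(2L, 3L))
  expect_equal(sum(g2$adj), 2L)
  zb <- (bulk$values[two, "s3"] - mean(bulk$values[two, ])) /
    stats::sd(bulk$values[two, ])
  expect_equal(unname(g2$features[two, "bulk_z"]), zb)
  expect_equal(unname(g2$features[two, "sc_mean"]), mean(sc$values[two, ]))
  expect_equal(unname(g2$features[two, "sc_detect"]),
               mean(sc$values[two, ] != 0))
  expect_error(build_sample_graph("s1", c(ids[1], "nope"), fused, bulk, sc),
               "input error")
  expect_error(build_sample_graph("zz", ids, fused, bulk, sc), "input error")
})
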