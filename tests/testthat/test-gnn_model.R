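test_that("attention coefficients are a softmax over the neighbourhood", {
  set.seed(30)
  # singleton: self-loop only, coefficient 1
  H1 <- matrix(rnorm(3), 1, 3)
  r1 <- gat_layer(H1, matrix(0L, 1, 1), W = matrix(rnorm(6), 3, 2),
                  a_src = matrix(rnorm(2)), a_dst = matrix(rnorm(2)))
  expect_equal(r1$attention[[1]][1, 1], 1)
  # two neighbours with features identical to self: uniform attention
  H3 <- matrix(rep(c(1, -2, 0.5), each = 3), 3, 3)
  adj3 <- matrix(1L, 3, 3); diag(adj3) <- 0L
  W <- matrix(rnorm(6), 3, 2)
  a1 <- matrix(rnorm(2)); a2 <- matrix(rnorm(2))
  r3 <- gat_layer(H3, adj3, W, a1, a2)
  expect_equal(unname(r3$attention[[1]]), matrix(1 / 3, 3, 3),
               tolerance = 1e-12)
  r3b <- gat_layer(H3, adj3, W, a1, a2, self_loops = FALSE)
  expect_equal(sort(unique(round(as.vector(r3b$attention[[1]]), 10))),
               c(0, 0.5))
  # random graphs: every row sums to one over the masked neighbourhood
  for (r in 1:5) {
    g <- fx_graph(sample(4:9, 1), seed = 40 + r)
    res <- gat_layer(g$features, g$adj,
                     W = list(matrix(rnorm(6), 3, 2), matrix(rnorm(6), 3, 2)),
                     a_src = list(matrix(rnorm(2)), matrix(rnorm(2))),
                     a_dst = list(matrix(rnorm(2)), matrix(rnorm(2))))
    for (h in 1:2)
      expect_equal(rowSums(res$attention[[h]]), rep(1, nrow(g$adj)),
                   tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("the GAT layer reproduces a straight-line evaluation", {
  set.seed(31)
  n <- 5; f <- 3; fp <- 4
  g <- fx_graph(n, p = 0.5, seed = 77)
  H <- g$features
  W <- matrix(rnorm(f * fp), f, fp)
  a1 <- matrix(rnorm(fp)); a2 <- matrix(rnorm(fp))
  res <- gat_layer(H, g$adj, W, a1, a2, slope = 0.2)
  # independent step-by-step oracle with explicit loops
  Wh <- H %*% W
  mask <- (g$adj + diag(n)) > 0
  att_or <- matrix(0, n, n)
  for (i in 1:n) {
    e <- rep(-Inf, n)
    for (j in 1:n) {
      if (!mask[i, j]) next
      raw <- sum(a1 * Wh[i, ]) + sum(a2 * Wh[j, ])
      e[j] <- if (raw > 0) raw else 0.2 * raw
    }
    ex <- exp(e - max(e[mask[i, ]]))
    ex[!mask[i, ]] <- 0
    att_or[i, ] <- ex / sum(ex)
  }
  Hout <- att_or %*% Wh
  Hout <- ifelse(Hout > 0, Hout, exp(Hout) - 1)
  expect_lt(max(abs(res$attention[[1]] - att_or)), 1e-6)
  expect_lt(max(abs(res$H - Hout)), 1e-6)
})

test_that("MinCut pooling losses hit their analytic landmarks", {
  # two disconnected equal cliques with the exact indicator assignment
  blk <- matrix(1L, 4, 4); diag(blk) <- 0L
  adj <- rbind(cbind(blk, matrix(0L, 4, 4)),
               cbind(matrix(0L, 4, 4), blk))
  S <- rbind(matrix(rep(c(1, 0), each = 4), 4, 2),
             matrix(rep(c(0, 1), each = 4), 4, 2))
  H <- matrix(rnorm(16), 8, 2)
  res <- mincut_pool(H, adj, S)
  expect_equal(res$l_cut, -1)
  expect_equal(res$l_ortho, 0, tolerance = 1e-12)
  expect_equal(res$H_pool, t(S) %*% H)
  # uniform assignment: compare against direct dense arithmetic
  K <- 3; n <- 6
  set.seed(32)
  g <- fx_graph(n, p = 0.6, seed = 99)
  Su <- matrix(1 / K, n, K)
  ru <- mincut_pool(g$features, g$adj, Su)
  D <- diag(rowSums(g$adj))
  expect_equal(ru$l_cut,
               -sum(diag(t(Su) %*% g$adj %*% Su)) /
                 sum(diag(t(Su) %*% D %*% Su)))
  StS <- t(Su) %*% Su
  expect_equal(ru$l_ortho,
               norm(StS / norm(StS, "F") - diag(K) / sqrt(K), "F"))
  # K = 1 degenerates to a single node with l_cut = -1
  S1 <- matrix(1, n, 1)
  r1 <- mincut_pool(g$features, g$adj, S1)
  expect_equal(r1$l_cut, -1)
  expect_equal(dim(r1$A_pool), c(1L, 1L))
  expect_error(mincut_pool(H, adj, S * 2), "row-stochastic")
})

test_that("pooling losses stay in their theoretical ranges", {
  set.seed(33)
  for (r in 1:20) {
    n <- sample(4:12, 1); K <- sample(2:4, 1)
    g <- fx_graph(n, p = runif(1, 0.2, 0.8), seed = 200 + r)
    S <- matrix(rexp(n * K), n, K)
    S <- S / rowSums(S)
    res <- mincut_pool(g$features, g$adj, S)
    expect_gte(res$l_cut, -1 - 1e-12)
    expect_lte(res$l_cut, 0)
    expect_gte(res$l_ortho, 0)
    expect_lte(res$l_ortho, sqrt(2) + 1e-12)
  }
})

test_that("transformer encoder collapses to layer norm at zero weights", {
  cf <- gnn_config(hidden = 4, gat_heads = 2, K = 2, d_model = 4,
                   tf_heads = 2, tf_layers = 2, d_ff = 8, pe_dim = 1)
  m <- gnn_init(cf, seed = 1)
  for (nm in names(m$params)) {
    if (grepl("^tf\\d_(Wq|Wk|Wv|Wo|bo|W1|b1|W2|b2)", nm))
      m$params[[nm]] <- m$params[[nm]] * 0
  }
  set.seed(34)
  Z <- matrix(rnorm(12), 3, 4)
  out <- transformer_encode(Z, m)
  ln <- function(X) {
    mu <- rowMeans(X); v <- rowMeans((X - mu)^2)
    (X - mu) / sqrt(v + 1e-5)
  }
  expect_equal(out, ln(ln(ln(ln(Z)))), tolerance = 1e-10)
  # shift invariance: a constant added to every feature vanishes in LN
  expect_equal(transformer_encode(Z + 3.7, m), out, tolerance = 1e-8)
})

test_that("a single attention head matches a hand-traced computation", {
  cf <- gnn_config(hidden = 4, gat_heads = 2, K = 2, d_model = 2,
                   tf_heads = 1, tf_layers = 1, d_ff = 2, pe_dim = 1)
  m <- gnn_init(cf, seed = 2)
  Wq <- matrix(c(1, 0, 0.5, -1), 2, 2)
  Wk <- matrix(c(0.2, 1, -0.3, 0.4), 2, 2)
  Wv <- matrix(c(1, 1, 0, -0.5), 2, 2)
  Wo <- diag(2); W1 <- matrix(c(0.3, -0.2, 1, 0.1), 2, 2)
  W2 <- matrix(c(0.5, 0.5, -1, 0.2), 2, 2)
  m$params$tf1_Wq1 <- Wq; m$params$tf1_Wk1 <- Wk; m$params$tf1_Wv1 <- Wv
  m$params$tf1_Wo <- Wo; m$params$tf1_bo <- matrix(0, 1, 2)
  m$params$tf1_W1 <- W1; m$params$tf1_b1 <- matrix(0, 1, 2)
  m$params$tf1_W2 <- W2; m$params$tf1_b2 <- matrix(0, 1, 2)
  Z <- matrix(c(1, -1, 0.5, 2), 2, 2)
  out <- transformer_encode(Z, m)
  # hand trace
  Q <- Z %*% Wq; K <- Z %*% Wk; V <- Z %*% Wv
  Sc <- Q %*% t(K) / sqrt(2)
  P <- exp(Sc - apply(Sc, 1, max))
  P <- P / rowSums(P)
  msa <- (P %*% V) %*% Wo
  ln <- function(X) {
    mu <- rowMeans(X); v <- rowMeans((X - mu)^2)
    (X - mu) / sqrt(v + 1e-5)
  }
  Z1 <- ln(Z + msa)
  ff <- pmax(Z1 %*% W1, 0) %*% W2
  expect_lt(max(abs(out - ln(Z1 + ff))), 1e-6)
})

test_that("forward pass is permutation invariant and deterministic", {
  cf <- fx_small_config()
  m <- gnn_init(cf, seed = 3)
  for (r in 1:5) {
    g <- fx_graph(sample(6:12, 1), seed = 300 + r)
    out <- gnn_forward(m, g)
    n <- length(g$nodes)
    perm <- sample(n)
    gp <- g
    gp$nodes <- g$nodes[perm]
    gp$features <- g$features[perm, , drop = FALSE]
    gp$adj <- g$adj[perm, perm]
    outp <- gnn_forward(m, gp)
    expect_equal(outp$theta, out$theta, tolerance = 1e-5)
    # attention permutes consistently with the nodes
    expect_equal(outp$attention[[1]][[1]],
                 out$attention[[1]][[1]][perm, perm], tolerance = 1e-6)
  }
  # zero network scores zero
  mz <- m
  for (nm in names(mz$params)) mz$params[[nm]] <- mz$params[[nm]] * 0
  g <- fx_graph(7, seed = 55)
  expect_equal(gnn_forward(mz, g)$theta, 0)
  # bitwise determinism
  expect_identical(gnn_forward(m, g)$theta, gnn_forward(m, g)$theta)
  # pooling assignment is row-stochastic
  out <- gnn_forward(m, g)
  expect_equal(rowSums(out$pooling), rep(1, 7), tolerance = 1e-6)
})
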