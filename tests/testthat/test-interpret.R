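test_that("attention aggregation matches forced arithmetic and means", {
  a <- matrix(c(0, 1, 1, 0), 2, 2)  # a_12 = a_21 = 1, zero self mass
  r1 <- fx_record("s1", c("gA", "gB"), list(list(a)))
  r2 <- fx_record("s2", c("gA", "gB"), list(list(a)))
  agg <- aggregate_attention(list(r1, r2), c(s1 = "high", s2 = "low"))
  expect_equal(unname(agg$edge_w[, "gA|gB"]), c(1, 1))
  expect_equal(unname(agg$node_imp[1, ]), c(1, 1))
  # two identical samples: the global mean equals either sample's table
  expect_equal(colMeans(agg$edge_w), agg$edge_w[1, ], ignore_attr = TRUE)
  expect_error(aggregate_attention(list(r1, r2),
                                   c(s1 = "high", s2 = "high")),
               "empty risk cohort")
})

test_that("aggregation equals a brute-force accumulation loop", {
  set.seed(60)
  genes <- sprintf("g%02d", 1:8)
  records <- lapply(1:6, function(s) {
    nodes <- sort(sample(genes, sample(4:8, 1)))
    n <- length(nodes)
    layers <- lapply(1:2, function(l) lapply(1:2, function(h) {
      m <- matrix(runif(n * n), n, n)
      m / rowSums(m)
    }))
    fx_record(sprintf("s%d", s), nodes, layers)
  })
  groups <- setNames(rep(c("high", "low"), 3), sprintf("s%d", 1:6))
  agg <- aggregate_attention(records, groups)
  # oracle: accumulate every edge weight by explicit loops
  for (s in seq_along(records)) {
    r <- records[[s]]
    n <- length(r$nodes)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      w <- 0; cnt <- 0
      for (l in 1:2) for (h in 1:2) {
        w <- w + (r$attention[[l]][[h]][i, j] +
                    r$attention[[l]][[h]][j, i]) / 2
        cnt <- cnt + 1
      }
      key <- paste(sort(c(r$nodes[i], r$nodes[j])), collapse = "|")
      expect_equal(agg$edge_w[s, key], w / cnt)
    }
    # node importance is the sum of incident edge weights
    for (i in seq_len(n)) {
      tot <- 0
      for (j in seq_len(n)) {
        if (j == i) next
        key <- paste(sort(c(r$nodes[i], r$nodes[j])), collapse = "|")
        tot <- tot + agg$edge_w[s, key]
      }
      expect_equal(agg$node_imp[s, r$nodes[i]], tot, tolerance = 1e-12)
    }
  }
  # handshake identity: importances count every edge twice
  expect_equal(sum(agg$node_imp), 2 * sum(agg$edge_w), tolerance = 1e-9)
})

test_that("node statistics flag high-risk dominated hubs", {
  # node gA-gB edge heavy in high-risk samples only; gC-gD background
  mk <- function(id, w) {
    m <- matrix(0, 4, 4)
    m[1, 2] <- m[2, 1] <- w
    m[3, 4] <- m[4, 3] <- 0.05
    m[1, 3] <- m[3, 1] <- 0.02  # connects the graph
    fx_record(id, c("gA", "gB", "gC", "gD"), list(list(m)))
  }
  records <- c(lapply(1:5, function(i) mk(sprintf("h%d", i), 0.9 + 0.01 * i)),
               lapply(1:5, function(i) mk(sprintf("l%d", i), 0.05 + 0.01 * i)))
  groups <- setNames(rep(c("high", "low"), each = 5),
                     vapply(records, function(r) r$sample_id, ""))
  agg <- aggregate_attention(records, groups)
  ns <- node_analysis(agg, top_q = 0.5)
  rownames(ns) <- ns$gene_id
  expect_equal(ns["gC", "risk_bias"], 0)   # symmetric background
  expect_equal(ns["gC", "log_fc"], 0)
  expect_gt(ns["gA", "risk_bias"], 0.5)
  expect_equal(ns["gA", "risk_class"], "high")
  expect_true(ns["gA", "is_key"])
  expect_true(all(abs(ns$risk_bias) <= 1))
  # boundary: importance absent from low-risk cohort drives bias to 1
  only_hi <- c(lapply(1:4, function(i) mk(sprintf("h%d", i), 1)),
               list(fx_record("l1", c("gA", "gB"),
                              list(list(matrix(c(0, 1e-9, 1e-9, 0), 2))))))
  agg2 <- aggregate_attention(only_hi,
                              setNames(c(rep("high", 4), "low"),
                                       c(sprintf("h%d", 1:4), "l1")))
  ns2 <- suppressWarnings(node_analysis(agg2))
  expect_gt(ns2$risk_bias[ns2$gene_id == "gC"], 0.999)
})

test_that("edge statistics honour the strict driver thresholds", {
  mk2 <- function(id, nodes, w) {
    n <- length(nodes)
    m <- matrix(0, n, n)
    m[1, 2] <- m[2, 1] <- w
    if (n > 2) m[2, 3] <- m[3, 2] <- 0.3
    fx_record(id, nodes, list(list(m)))
  }
  # edge gX|gY present in all samples with equal weight in both cohorts
  rec <- c(lapply(1:5, function(i) mk2(sprintf("h%d", i), c("gX", "gY", "gZ"), 0.4)),
           lapply(1:5, function(i) mk2(sprintf("l%d", i), c("gX", "gY", "gZ"), 0.4)))
  groups <- setNames(rep(c("high", "low"), each = 5),
                     vapply(rec, function(r) r$sample_id, ""))
  agg <- aggregate_attention(rec, groups)
  ns <- node_analysis(agg, top_q = 1)  # every node passes the rankings
  es <- edge_analysis(agg, ns)
  r1 <- es[es$gene_a == "gX" & es$gene_b == "gY", ]
  expect_equal(r1$frequency, 1)
  expect_equal(r1$risk_specificity, 0.5, tolerance = 1e-9)
  expect_false(r1$is_driver)  # strict > 0.5
  expect_equal(r1$global_weight, 10 * 0.4)
  # edge only in high-risk samples, 30% of the cohort
  rec2 <- c(lapply(1:3, function(i) mk2(sprintf("h%d", i), c("gP", "gQ"), 0.8)),
            lapply(1:7, function(i) mk2(sprintf("l%d", i), c("gX", "gY"), 0.5)))
  groups2 <- setNames(c(rep("high", 3), rep("low", 7)),
                      vapply(rec2, function(r) r$sample_id, ""))
  agg2 <- aggregate_attention(rec2, groups2)
  ns2 <- node_analysis(agg2, top_q = 1)
  ns2$is_key <- TRUE  # isolate the edge criteria from the node screen
  es2 <- edge_analysis(agg2, ns2)
  r2 <- es2[es2$gene_a == "gP", ]
  expect_equal(r2$frequency, 0.3)
  expect_gt(r2$risk_specificity, 0.999)
  expect_true(r2$is_driver)
  # brute-force recomputation of all statistics
  for (k in seq_len(nrow(es2))) {
    w <- agg2$edge_w[, paste(es2$gene_a[k], es2$gene_b[k], sep = "|")]
    hi <- groups2[rownames(agg2$edge_w)] == "high"
    expect_equal(es2$global_weight[k], sum(w))
    expect_equal(es2$frequency[k], mean(w > 0))
    expect_equal(es2$influence[k], mean(w) * mean(w > 0))
    expect_equal(es2$risk_specificity[k],
                 mean(w[hi]) / (mean(w[hi]) + mean(w[!hi]) + 1e-12))
  }
})

test_that("Louvain modules recover planted structure", {
  # two disconnected 4-cliques
  cl <- expand.grid(a = 1:4, b = 1:4)
  cl <- cl[cl$a < cl$b, ]
  edges <- data.frame(
    gene_a = c(paste0("a", cl$a), paste0("b", cl$a)),
    gene_b = c(paste0("a", cl$b), paste0("b", cl$b)),
    global_weight = 1, stringsAsFactors = FALSE)
  nodes <- data.frame(gene_id = c(paste0("a", 1:4), paste0("b", 1:4)),
                      risk_class = rep(c("high", "low"), each = 4),
                      stringsAsFactors = FALSE)
  rep_ <- module_analysis(edges, nodes)
  expect_equal(nrow(rep_$modules), 2)
  expect_equal(rep_$modules$density, c(1, 1))
  expect_equal(sort(rep_$modules$high_risk_fraction), c(0, 1))
  # cross-group edges: none inside pure-risk cliques
  expect_equal(nrow(rep_$cross_group_edges), 0)
  # modularity beats the one-module partition (which scores 0)
  expect_gt(rep_$modularity, 0)
  # planted two-block weighted network, 10 seeds
  set.seed(61)
  n <- 16
  block <- rep(1:2, each = n / 2)
  ids <- sprintf("n%02d", 1:n)
  ea <- c(); eb <- c(); w <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (block[i] == block[j]) { ea <- c(ea, ids[i]); eb <- c(eb, ids[j]); w <- c(w, 5) }
    else if (runif(1) < 0.2) { ea <- c(ea, ids[i]); eb <- c(eb, ids[j]); w <- c(w, 0.1) }
  }
  pe <- data.frame(gene_a = ea, gene_b = eb, global_weight = w,
                   stringsAsFactors = FALSE)
  pn <- data.frame(gene_id = ids, risk_class = rep(c("high", "low"), n / 2),
                   stringsAsFactors = FALSE)
  for (s in 1:10) {
    r <- module_analysis(pe, pn, seed = s)
    expect_equal(ari(r$membership[ids], block), 1)
  }
  # empty network degenerates gracefully
  r0 <- module_analysis(pe[0, ], pn)
  expect_equal(nrow(r0$modules), 0)
})
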