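# Attention-based interpretability: pool the trained model's edge
# attention into per-sample edge weights and node importances, compare
# high- vs low-risk cohorts at the node and edge level, and summarize
# the aggregate network with Louvain modules and cross-group driver
# edges.

#' Aggregate attention records across a cohort
#'
#' Per sample, the weight of an edge (i, j) is the mean over GAT
#' layers and heads of the symmetrized coefficient `(a_ij + a_ji)/2`;
#' self-attention mass is excluded so that node importance (the sum of
#' incident edge weights) satisfies the handshake identity: the sum of
#' node importances equals twice the sum of edge weights. Gene-level
#' tables are built on the union of all sample node sets, with absent
#' genes/edges contributing zero.
#'
#' @param records list of [gnn_forward()] outputs (one per sample)
#' @param risk_groups per-sample labels, `"high"`/`"low"`, named by or
#'   ordered as the records
#' @return A list of class `attention_aggregate`: `genes`, `edges`
#'   (data frame gene_a/gene_b), `node_imp` (samples x genes),
#'   `edge_w` (samples x edges), `groups`.
#' @export
aggregate_attention <- function(records, risk_groups) {
  ids <- vapply(records, function(r) r$sample_id, character(1))
  if (!is.null(names(risk_groups))) risk_groups <- risk_groups[ids]
  risk_groups <- as.character(risk_groups)
  if (length(risk_groups) != length(records) || anyNA(risk_groups))
    stop("input error: every sample needs a high/low label")
  if (!all(risk_groups %in% c("high", "low")))
    stop("input error: labels must be 'high' or 'low'")
  if (!any(risk_groups == "high") || !any(risk_groups == "low"))
    stop("estimation error: empty risk cohort")
  genes <- sort(unique(unlist(lapply(records, function(r) r$nodes))))
  edge_key <- character(0)
  sample_w <- vector("list", length(records))
  for (s in seq_along(records)) {
    r <- records[[s]]
    n <- length(r$nodes)
    acc <- matrix(0, n, n)
    cnt <- 0L
    for (l in seq_along(r$attention)) {
      for (h in seq_along(r$attention[[l]])) {
        a <- r$attention[[l]][[h]]
        acc <- acc + (a + t(a)) / 2
        cnt <- cnt + 1L
      }
    }
    W <- acc / cnt
    diag(W) <- 0
    idx <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
    ga <- r$nodes[idx[, 1]]; gb <- r$nodes[idx[, 2]]
    swap <- ga > gb
    tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
    key <- paste(ga, gb, sep = "|")
    sample_w[[s]] <- list(key = key, w = W[idx])
    edge_key <- union(edge_key, key)
  }
  edge_key <- sort(edge_key)
  edge_w <- matrix(0, length(records), length(edge_key),
                   dimnames = list(ids, edge_key))
  for (s in seq_along(records)) {
    edge_w[s, sample_w[[s]]$key] <- sample_w[[s]]$w
  }
  parts <- strsplit(edge_key, "|", fixed = TRUE)
  edges <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                      gene_b = vapply(parts, `[`, "", 2),
                      stringsAsFactors = FALSE)
  node_imp <- matrix(0, length(records), length(genes),
                     dimnames = list(ids, genes))
  for (g in seq_along(genes)) {
    inc <- edges$gene_a == genes[g] | edges$gene_b == genes[g]
    if (any(inc))
      node_imp[, g] <- rowSums(edge_w[, inc, drop = FALSE])
  }
  structure(list(genes = genes, edges = edges, node_imp = node_imp,
                 edge_w = edge_w, groups = risk_groups),
            class = "attention_aggregate")
}

#' Node-level statistics and tri-criteria key-node screen
#'
#' Cohort importances are means of per-sample node importance over all
#' / high-risk / low-risk samples. Risk bias is the normalized high-low
#' contrast, log fold-change is `log2` of the (epsilon-guarded) ratio,
#' and centrality is degree centrality in the aggregate network.
#' Differential significance comes from a Mann-Whitney rank-sum test
#' of per-sample importances between cohorts, BH-adjusted. A node is a
#' key node when its global importance and centrality both sit in the
#' top `top_q` quantile and its differential FDR is below 0.05.
#'
#' @param agg an [aggregate_attention()] result
#' @param top_q top quantile for the ranking criteria (default 0.25)
#' @param eps stabilizer in the bias/fold-change ratios
#' @return Data frame of class `node_stats`, one row per gene.
#' @export
node_analysis <- function(agg, top_q = 0.25, eps = 1e-12) {
  hi <- agg$groups == "high"
  imp_g <- colMeans(agg$node_imp)
  imp_h <- colMeans(agg$node_imp[hi, , drop = FALSE])
  imp_l <- colMeans(agg$node_imp[!hi, , drop = FALSE])
  risk_bias <- (imp_h - imp_l) / (imp_h + imp_l + eps)
  log_fc <- log2((imp_h + eps) / (imp_l + eps))
  ng <- length(agg$genes)
  deg <- integer(ng)
  names(deg) <- agg$genes
  tab <- table(c(agg$edges$gene_a, agg$edges$gene_b))
  deg[names(tab)] <- as.integer(tab)
  centrality <- if (ng > 1) deg / (ng - 1) else rep(0, ng)
  diff_p <- rep(NA_real_, ng)
  enough <- sum(hi) >= 3 && sum(!hi) >= 3
  if (enough) {
    for (g in seq_len(ng)) {
      diff_p[g] <- suppressWarnings(
        stats::wilcox.test(agg$node_imp[hi, g],
                           agg$node_imp[!hi, g], exact = FALSE)$p.value)
    }
    diff_p[!is.finite(diff_p)] <- 1
  } else {
    warning("fewer than 3 samples per risk group; differential test skipped")
  }
  diff_fdr <- if (enough) bh_adjust(diff_p) else diff_p
  q_imp <- stats::quantile(imp_g, 1 - top_q, names = FALSE)
  q_cen <- stats::quantile(centrality, 1 - top_q, names = FALSE)
  is_key <- imp_g >= q_imp & centrality >= q_cen &
    !is.na(diff_fdr) & diff_fdr < 0.05
  out <- data.frame(gene_id = agg$genes,
                    importance_global = imp_g,
                    importance_high = imp_h,
                    importance_low = imp_l,
                    risk_bias = risk_bias,
                    log_fc = log_fc,
                    centrality = centrality,
                    diff_fdr = diff_fdr,
                    is_key = is_key,
                    risk_class = ifelse(risk_bias > 0, "high", "low"),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("node_stats", "data.frame")
  out
}

#' Edge-level statistics and driver-edge screen
#'
#' Global weight is the across-sample sum of symmetrized attention;
#' frequency is the proportion of sample graphs containing the edge;
#' risk specificity is the high-risk share of the edge's mean cohort
#' weight; influence is mean weight times frequency. A driver edge has
#' risk specificity > `spec_threshold`, frequency > `freq_threshold`
#' (both strict) and both endpoints flagged as key nodes.
#'
#' @param agg an [aggregate_attention()] result
#' @param nodes a [node_analysis()] result (for the key-node filter)
#' @param spec_threshold risk-specificity threshold (default 0.5)
#' @param freq_threshold frequency threshold (default 0.2)
#' @param eps stabilizer for the specificity ratio
#' @return Data frame of class `edge_stats`, one row per edge.
#' @export
edge_analysis <- function(agg, nodes, spec_threshold = 0.5,
                          freq_threshold = 0.2, eps = 1e-12) {
  hi <- agg$groups == "high"
  gw <- colSums(agg$edge_w)
  freq <- colMeans(agg$edge_w > 0)
  mh <- colMeans(agg$edge_w[hi, , drop = FALSE])
  ml <- colMeans(agg$edge_w[!hi, , drop = FALSE])
  spec <- mh / (mh + ml + eps)
  infl <- colMeans(agg$edge_w) * freq
  key <- nodes$gene_id[nodes$is_key]
  both_key <- agg$edges$gene_a %in% key & agg$edges$gene_b %in% key
  out <- data.frame(gene_a = agg$edges$gene_a,
                    gene_b = agg$edges$gene_b,
                    global_weight = gw,
                    frequency = freq,
                    risk_specificity = spec,
                    influence = infl,
                    is_driver = spec > spec_threshold &
                      freq > freq_threshold & both_key,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("edge_stats", "data.frame")
  out
}

#' Louvain modules of the aggregate attention network
#'
#' Runs Louvain community detection on the aggregate network weighted
#' by global edge weight, then summarizes each module's topology, risk
#' composition and interaction strength, and lists its cross-group
#' edges (edges joining a high-risk to a low-risk node) sorted by
#' global weight.
#'
#' @param edges an [edge_analysis()] result
#' @param nodes a [node_analysis()] result
#' @param resolution Louvain resolution (default 1)
#' @param seed RNG seed (community detection order)
#' @return A list of class `module_report`: `membership` (named
#'   integer), `modularity`, `modules` (data frame: module, size,
#'   density, mean_edge_weight, high_risk_fraction, genes),
#'   `cross_group_edges` (data frame, weight-sorted).
#' @export
module_analysis <- function(edges, nodes, resolution = 1, seed = 1) {
  if (nrow(edges) == 0) {
    return(structure(list(membership = integer(0), modularity = NA_real_,
                          modules = data.frame(), cross_group_edges = data.frame()),
                     class = "module_report"))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = nodes$gene_id))
  igraph::E(g)$weight <- edges$global_weight
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  risk <- stats::setNames(nodes$risk_class, nodes$gene_id)
  mods <- sort(unique(as.integer(memb)))
  rows <- lapply(mods, function(m) {
    gs <- names(memb)[memb == m]
    within <- edges$gene_a %in% gs & edges$gene_b %in% gs
    size <- length(gs)
    dens <- if (size > 1) sum(within) / choose(size, 2) else 0
    data.frame(module = m, size = size, density = dens,
               mean_edge_weight = if (any(within))
                 mean(edges$global_weight[within]) else 0,
               high_risk_fraction = mean(risk[gs] == "high"),
               genes = paste(sort(gs), collapse = ","),
               stringsAsFactors = FALSE)
  })
  cross <- edges[risk[edges$gene_a] != risk[edges$gene_b], , drop = FALSE]
  cross <- cross[order(-cross$global_weight), , drop = FALSE]
  structure(list(membership = memb,
                 modularity = igraph::modularity(comm),
                 modules = do.call(rbind, rows),
                 cross_group_edges = cross),
            class = "module_report")
}
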