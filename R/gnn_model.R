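# Graph network mapping a sample graph to a scalar risk score:
# input projection -> 2 graph-attention layers -> MinCut pooling ->
# token sequence (pooled clusters + class token + spectral positional
# encodings) -> 2 Transformer encoder layers -> linear head on the
# class token. Forward passes run on the autodiff tape (R/ad.R) so the
# trainer gets exact gradients.

#' Network architecture configuration
#'
#' Sizes are deliberately compact so full-cohort training is practical
#' on a single CPU; every value can be raised for larger machines.
#' `hidden` must be divisible by `gat_heads`, and `d_model` by
#' `tf_heads`.
#'
#' @param f_in node feature dimension (3 for [build_sample_graph()])
#' @param hidden GAT hidden width (heads concatenated)
#' @param gat_heads attention heads per GAT layer
#' @param gat_layers number of GAT layers
#' @param slope LeakyReLU negative slope in attention scoring
#' @param K number of pooled clusters
#' @param d_model Transformer token width
#' @param tf_heads,tf_layers,d_ff Transformer shape
#' @param pe_dim number of Laplacian eigenvectors used as positional
#'   encodings of the pooled graph
#' @return A list of class `gnn_config`.
#' @export
gnn_config <- function(f_in = 3, hidden = 16, gat_heads = 4, gat_layers = 2,
                       slope = 0.2, K = 8, d_model = 16, tf_heads = 2,
                       tf_layers = 2, d_ff = 32, pe_dim = 4) {
  if (hidden %% gat_heads != 0)
    stop("config error: hidden must be divisible by gat_heads")
  if (d_model %% tf_heads != 0)
    stop("config error: d_model must be divisible by tf_heads")
  structure(list(f_in = f_in, hidden = hidden, gat_heads = gat_heads,
                 gat_layers = gat_layers, slope = slope, K = K,
                 d_model = d_model, tf_heads = tf_heads,
                 tf_layers = tf_layers, d_ff = d_ff, pe_dim = pe_dim),
            class = "gnn_config")
}

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize network parameters
#'
#' Glorot-uniform weights, zero biases, unit layer-norm gains;
#' deterministic given `seed`.
#'
#' @param config a [gnn_config()]
#' @param seed integer RNG seed
#' @return A list of class `gnn_model` with `params` (named matrices)
#'   and `config`.
#' @export
gnn_init <- function(config = gnn_config(), seed = 1) {
  set.seed(seed)
  cf <- config
  hh <- cf$hidden / cf$gat_heads
  dk <- cf$d_model / cf$tf_heads
  p <- list(
    Win = .glorot(cf$f_in, cf$hidden),
    bin = matrix(0, 1, cf$hidden)
  )
  for (l in seq_len(cf$gat_layers)) {
    for (h in seq_len(cf$gat_heads)) {
      p[[sprintf("gat%d_W%d", l, h)]] <- .glorot(cf$hidden, hh)
      p[[sprintf("gat%d_a1%d", l, h)]] <- .glorot(hh, 1)
      p[[sprintf("gat%d_a2%d", l, h)]] <- .glorot(hh, 1)
    }
  }
  p$pool_W <- .glorot(cf$hidden, cf$K)
  p$pool_b <- matrix(0, 1, cf$K)
  p$proj_W <- .glorot(cf$hidden, cf$d_model)
  p$proj_b <- matrix(0, 1, cf$d_model)
  p$cls <- matrix(stats::rnorm(cf$d_model, sd = 0.02), 1, cf$d_model)
  for (l in seq_len(cf$tf_layers)) {
    for (h in seq_len(cf$tf_heads)) {
      p[[sprintf("tf%d_Wq%d", l, h)]] <- .glorot(cf$d_model, dk)
      p[[sprintf("tf%d_Wk%d", l, h)]] <- .glorot(cf$d_model, dk)
      p[[sprintf("tf%d_Wv%d", l, h)]] <- .glorot(cf$d_model, dk)
    }
    p[[sprintf("tf%d_Wo", l)]] <- .glorot(cf$d_model, cf$d_model)
    p[[sprintf("tf%d_bo", l)]] <- matrix(0, 1, cf$d_model)
    p[[sprintf("tf%d_ln1g", l)]] <- matrix(1, 1, cf$d_model)
    p[[sprintf("tf%d_ln1b", l)]] <- matrix(0, 1, cf$d_model)
    p[[sprintf("tf%d_W1", l)]] <- .glorot(cf$d_model, cf$d_ff)
    p[[sprintf("tf%d_b1", l)]] <- matrix(0, 1, cf$d_ff)
    p[[sprintf("tf%d_W2", l)]] <- .glorot(cf$d_ff, cf$d_model)
    p[[sprintf("tf%d_b2", l)]] <- matrix(0, 1, cf$d_model)
    p[[sprintf("tf%d_ln2g", l)]] <- matrix(1, 1, cf$d_model)
    p[[sprintf("tf%d_ln2b", l)]] <- matrix(0, 1, cf$d_model)
  }
  p$out_w <- .glorot(cf$d_model, 1)
  p$out_b <- matrix(0, 1, 1)
  structure(list(params = p, config = cf), class = "gnn_model")
}

# one GAT layer on the tape; pn = list(W=, a1=, a2= node lists per head)
.gat_layer_tape <- function(tape, H, mask, pn, slope) {
  heads <- length(pn$W)
  outs <- vector("list", heads)
  attn <- vector("list", heads)
  for (h in seq_len(heads)) {
    Wh <- ad_matmul(H, pn$W[[h]])
    e <- ad_outer_sum(ad_matmul(Wh, pn$a1[[h]]), ad_matmul(Wh, pn$a2[[h]]))
    e <- ad_leakyrelu(e, slope)
    a <- ad_softmax_rows(e, mask)
    attn[[h]] <- ad_value(a)
    outs[[h]] <- ad_elu(ad_matmul(a, Wh))
  }
  list(H = ad_cbind_list(outs), attn = attn)
}

# Laplacian-eigenvector positional encodings of the discretized pooled
# graph; returns a (K+1) x d_model constant matrix (class-token row 0).
.pooled_pe <- function(Sval, adj, K, pe_dim, d_model) {
  assign <- max.col(Sval, ties.method = "first")
  Ap <- matrix(0, K, K)
  idx <- which(adj > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    a <- assign[idx[, 1]]; b <- assign[idx[, 2]]
    keep <- a != b
    if (any(keep)) {
      for (e in which(keep)) Ap[a[e], b[e]] <- 1
      Ap <- 1 * ((Ap + t(Ap)) > 0)
    }
  }
  L <- diag(rowSums(Ap)) - Ap
  ev <- eigen(L, symmetric = TRUE)
  ord <- order(ev$values)              # ascending; first is trivial
  take <- ord[seq(2, length.out = min(pe_dim, K - 1))]
  V <- ev$vectors[, take, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  PE <- matrix(0, K + 1, d_model)
  if (ncol(V)) PE[-1, seq_len(ncol(V))] <- V
  PE
}

# multi-head self-attention + FFN encoder layers on the tape
.tf_encode_tape <- function(tape, Z, pn, cf) {
  dk <- cf$d_model / cf$tf_heads
  for (l in seq_len(cf$tf_layers)) {
    g <- function(nm) pn[[sprintf("tf%d_%s", l, nm)]]
    hs <- vector("list", cf$tf_heads)
    for (h in seq_len(cf$tf_heads)) {
      Q <- ad_matmul(Z, pn[[sprintf("tf%d_Wq%d", l, h)]])
      K <- ad_matmul(Z, pn[[sprintf("tf%d_Wk%d", l, h)]])
      V <- ad_matmul(Z, pn[[sprintf("tf%d_Wv%d", l, h)]])
      A <- ad_softmax_rows(ad_scale(ad_matmul(Q, ad_t(K)), 1 / sqrt(dk)))
      hs[[h]] <- ad_matmul(A, V)
    }
    msa <- ad_add_rowvec(ad_matmul(ad_cbind_list(hs), g("Wo")), g("bo"))
    Z1 <- ad_layernorm_rows(ad_add(Z, msa), g("ln1g"), g("ln1b"))
    ff <- ad_add_rowvec(
      ad_matmul(ad_relu(ad_add_rowvec(ad_matmul(Z1, g("W1")), g("b1"))),
                g("W2")), g("b2"))
    Z <- ad_layernorm_rows(ad_add(Z1, ff), g("ln2g"), g("ln2b"))
  }
  Z
}

# full forward pass on an existing tape with parameter nodes pn.
# Returns nodes for theta / l_cut / l_ortho plus recorded values.
.gnn_forward_tape <- function(tape, pn, graph, cf) {
  n <- nrow(graph$features)
  adj <- graph$adj
  mask <- (adj + diag(n)) > 0   # self-loops so every row is defined
  X <- ad_const(tape, graph$features)
  H <- ad_add_rowvec(ad_matmul(X, pn$Win), pn$bin)
  attn <- vector("list", cf$gat_layers)
  for (l in seq_len(cf$gat_layers)) {
    gl <- list(
      W = lapply(seq_len(cf$gat_heads),
                 function(h) pn[[sprintf("gat%d_W%d", l, h)]]),
      a1 = lapply(seq_len(cf$gat_heads),
                  function(h) pn[[sprintf("gat%d_a1%d", l, h)]]),
      a2 = lapply(seq_len(cf$gat_heads),
                  function(h) pn[[sprintf("gat%d_a2%d", l, h)]]))
    res <- .gat_layer_tape(tape, H, mask, gl, cf$slope)
    H <- res$H
    attn[[l]] <- res$attn
  }
  # MinCut pooling
  S <- ad_softmax_rows(ad_add_rowvec(ad_matmul(H, pn$pool_W), pn$pool_b))
  Sval <- ad_value(S)
  Hp <- ad_matmul(ad_t(S), H)
  deg <- rowSums(adj)
  if (sum(adj) > 0) {
    An <- ad_const(tape, adj * 1)
    Dn <- ad_const(tape, diag(deg))
    num <- ad_trace(ad_matmul(ad_t(S), ad_matmul(An, S)))
    den <- ad_trace(ad_matmul(ad_t(S), ad_matmul(Dn, S)))
    l_cut <- ad_scale(ad_div(num, den), -1)
  } else {
    l_cut <- ad_const(tape, matrix(0, 1, 1))  # edgeless graph: flagged 0
  }
  StS <- ad_matmul(ad_t(S), S)
  fro <- ad_pow(ad_sum(ad_mul(StS, StS)), 0.5)
  diffm <- ad_addc(ad_scale_node(StS, ad_pow(fro, -1)),
                   -diag(cf$K) / sqrt(cf$K))
  l_ortho <- ad_pow(ad_sum(ad_mul(diffm, diffm)), 0.5)
  # tokens: class token + projected clusters + spectral encodings
  Tok <- ad_rbind2(pn$cls, ad_add_rowvec(ad_matmul(Hp, pn$proj_W), pn$proj_b))
  PE <- .pooled_pe(Sval, adj, cf$K, cf$pe_dim, cf$d_model)
  Tok <- ad_addc(Tok, PE)
  Z <- .tf_encode_tape(tape, Tok, pn, cf)
  theta <- ad_add(ad_matmul(ad_rows(Z, 1), pn$out_w), pn$out_b)
  th <- ad_value(theta)[1, 1]
  if (!is.finite(th))
    stop("numerical error: non-finite risk score at output head")
  list(theta = theta, l_cut = l_cut, l_ortho = l_ortho,
       attn = attn, S = Sval)
}

.params_to_nodes <- function(tape, params, trainable = TRUE) {
  f <- if (trainable) ad_param else ad_const
  lapply(params, function(m) f(tape, m))
}

#' Run the network on one sample graph
#'
#' @param model a [gnn_init()] (or [fit_gnn()]) model
#' @param graph a [build_sample_graph()] result
#' @return A list of class `gnn_output`: `theta` (scalar risk score),
#'   `l_cut`, `l_ortho` (pooling regularizers), `attention` (per GAT
#'   layer, per head, the n x n coefficient matrix over the self-loop
#'   neighbourhood), `pooling` (row-stochastic assignment matrix S).
#' @export
gnn_forward <- function(model, graph) {
  tape <- ad_tape()
  pn <- .params_to_nodes(tape, model$params, trainable = FALSE)
  out <- .gnn_forward_tape(tape, pn, graph, model$config)
  structure(list(theta = ad_value(out$theta)[1, 1],
                 l_cut = ad_value(out$l_cut)[1, 1],
                 l_ortho = ad_value(out$l_ortho)[1, 1],
                 attention = out$attn,
                 pooling = out$S,
                 nodes = graph$nodes,
                 sample_id = graph$sample_id),
            class = "gnn_output")
}

#' One graph-attention layer (value-level)
#'
#' Computes attention logits `e_ij = LeakyReLU(a_src' W h_i +
#' a_dst' W h_j)` over each node's neighbourhood (self-loops included
#' unless disabled), softmax-normalizes them, and aggregates
#' neighbour features with an ELU output nonlinearity. Multi-head
#' inputs (lists of `W`, `a_src`, `a_dst`) are concatenated.
#'
#' @param H node feature matrix (n x F)
#' @param adj binary symmetric adjacency (n x n)
#' @param W projection matrix F x F', or a list of them (one per head)
#' @param a_src,a_dst attention vectors (F' x 1), or lists per head
#' @param slope LeakyReLU negative slope
#' @param self_loops include each node in its own neighbourhood
#' @return list with `H` (n x F'·heads) and `attention` (list per head
#'   of n x n coefficient matrices; each row sums to 1 over the
#'   neighbourhood).
#' @export
gat_layer <- function(H, adj, W, a_src, a_dst, slope = 0.2,
                      self_loops = TRUE) {
  if (!is.list(W)) { W <- list(W); a_src <- list(a_src); a_dst <- list(a_dst) }
  n <- nrow(H)
  mask <- if (self_loops) (adj + diag(n)) > 0 else adj > 0
  if (any(rowSums(mask) == 0))
    stop("definition error: node with empty neighbourhood; enable self_loops")
  tape <- ad_tape()
  pn <- list(W = lapply(W, ad_const, tape = tape),
             a1 = lapply(a_src, ad_const, tape = tape),
             a2 = lapply(a_dst, ad_const, tape = tape))
  res <- .gat_layer_tape(tape, ad_const(tape, H), mask, pn, slope)
  list(H = ad_value(res$H), attention = res$attn)
}

#' MinCut pooling (value-level)
#'
#' Given a row-stochastic assignment `S` (nodes x K), pools features
#' `H_pool = S'H` and adjacency `A_pool = S'AS` (diagonal zeroed, then
#' symmetrically degree-normalized), and evaluates the relaxed
#' normalized-cut loss `l_cut = -Tr(S'AS)/Tr(S'DS)` (in \[-1, 0\];
#' defined as 0 for an edgeless graph) and the orthogonality loss
#' `l_ortho = ||S'S/||S'S||_F - I/sqrt(K)||_F` (in \[0, sqrt(2)\]).
#'
#' @param H node features (n x d)
#' @param adj binary adjacency (n x n)
#' @param S row-stochastic assignment (n x K)
#' @return list `H_pool`, `A_pool`, `l_cut`, `l_ortho`.
#' @export
mincut_pool <- function(H, adj, S) {
  if (any(abs(rowSums(S) - 1) > 1e-6) || any(S < 0))
    stop("input error: S must be row-stochastic")
  K <- ncol(S)
  Hp <- t(S) %*% H
  Ap <- t(S) %*% adj %*% S
  if (sum(adj) > 0) {
    D <- diag(rowSums(adj))
    l_cut <- -sum(diag(Ap)) / sum(diag(t(S) %*% D %*% S))
  } else l_cut <- 0
  diag(Ap) <- 0
  dp <- rowSums(Ap)
  sc <- ifelse(dp > 0, 1 / sqrt(dp), 0)
  Ap <- Ap * outer(sc, sc)
  StS <- crossprod(S)
  l_ortho <- norm(StS / norm(StS, "F") - diag(K) / sqrt(K), "F")
  list(H_pool = Hp, A_pool = Ap, l_cut = l_cut, l_ortho = l_ortho)
}

#' Transformer encoder (value-level)
#'
#' Applies the model's encoder stack (multi-head self-attention and
#' feed-forward blocks, each followed by a residual connection and
#' layer normalization) to a token matrix. Token 0 is the class token;
#' positional encodings are expected to be added by the caller.
#'
#' @param tokens token matrix (tokens x d_model)
#' @param model a [gnn_init()] model holding the encoder weights
#' @return Encoded token matrix of the same shape.
#' @export
transformer_encode <- function(tokens, model) {
  cf <- model$config
  if (ncol(tokens) != cf$d_model)
    stop("config error: token width ", ncol(tokens),
         " does not match d_model ", cf$d_model)
  tape <- ad_tape()
  pn <- .params_to_nodes(tape, model$params, trainable = FALSE)
  ad_value(.tf_encode_tape(tape, ad_const(tape, tokens), pn, cf))
}
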