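# Minimal reverse-mode automatic differentiation on a dynamic tape.
#
# Values are always stored as base-R double matrices (scalars are 1x1).
# A node "needs grad" (ng) iff it is a parameter or has a parameter
# ancestor; operations between constant nodes collapse to constants so
# the backward sweep only touches the differentiable subgraph.

#' Create an empty autodiff tape
#'
#' The tape records every operation applied to nodes created on it, so
#' that [ad_backward()] can accumulate gradients of scalar outputs with
#' respect to parameter leaves. Used internally by the graph network,
#' and exported for testing and extension.
#'
#' @return An environment of class `ad_tape`.
#' @keywords internal
#' @export
ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$last <- NULL
  e$n <- 0L
  class(e) <- "ad_tape"
  e
}

# nodes are environments chained by $prev so pushing is O(1); the
# backward sweep walks the chain in reverse creation order and
# accumulates gradients on the nodes themselves
.ad_push <- function(tape, val, parents = NULL, bw = NULL, ng = FALSE) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$parents <- parents
  node$bw <- bw
  node$ng <- ng
  node$grad <- NULL
  node$tape <- tape
  node$prev <- tape$last
  tape$last <- node
  tape$n <- tape$n + 1L
  class(node) <- "ad"
  node
}

.as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.double(x), nrow = length(x))
}

#' @rdname ad_tape
#' @param tape an `ad_tape`
#' @param x numeric matrix (or vector, coerced to a column matrix)
#' @export
ad_const <- function(tape, x) .ad_push(tape, .as_mat(x))

#' @rdname ad_tape
#' @export
ad_param <- function(tape, x) .ad_push(tape, .as_mat(x), ng = TRUE)

#' Value of an autodiff node
#' @param x an `ad` node handle
#' @return The node's current value as a matrix.
#' @keywords internal
#' @export
ad_value <- function(x) x$val

#' Accumulated gradient of a node after [ad_backward()]
#' @param x an `ad` node handle
#' @return The gradient matrix, or `NULL` if the sweep never reached
#'   the node.
#' @keywords internal
#' @export
ad_grad <- function(x) x$grad

.ad_op <- function(parents, val, bw) {
  tape <- parents[[1]]$tape
  ng <- FALSE
  for (p in parents) if (p$ng) { ng <- TRUE; break }
  if (!ng) return(.ad_push(tape, val))
  .ad_push(tape, val, parents, bw, ng = TRUE)
}

## ---- elementwise and linear-algebra primitives ----

ad_add <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  .ad_op(list(a, b), av + bv, function(g) list(g, g))
}

ad_sub <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  .ad_op(list(a, b), av - bv, function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  .ad_op(list(a, b), av * bv, function(g) list(g * bv, g * av))
}

ad_matmul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  .ad_op(list(a, b), av %*% bv,
         function(g) list(g %*% t(bv), t(av) %*% g))
}

ad_t <- function(a) {
  .ad_op(list(a), t(ad_value(a)), function(g) list(t(g)))
}

# multiply by a fixed scalar
ad_scale <- function(a, k) {
  .ad_op(list(a), k * ad_value(a), function(g) list(k * g))
}

# add a fixed matrix/scalar
ad_addc <- function(a, C) {
  .ad_op(list(a), ad_value(a) + C, function(g) list(g))
}

ad_pow <- function(a, p) {
  av <- ad_value(a)
  .ad_op(list(a), av^p, function(g) list(g * p * av^(p - 1)))
}

ad_exp <- function(a) {
  v <- exp(ad_value(a))
  .ad_op(list(a), v, function(g) list(g * v))
}

ad_log <- function(a) {
  av <- ad_value(a)
  .ad_op(list(a), log(av), function(g) list(g / av))
}

ad_sum <- function(a) {
  av <- ad_value(a)
  .ad_op(list(a), matrix(sum(av), 1, 1),
         function(g) list(matrix(g[1, 1], nrow(av), ncol(av))))
}

ad_trace <- function(a) {
  av <- ad_value(a)
  n <- nrow(av)
  .ad_op(list(a), matrix(sum(diag(av)), 1, 1),
         function(g) list(diag(g[1, 1], n)))
}

# X (n x m) + row vector r (1 x m), broadcast down rows
ad_add_rowvec <- function(X, r) {
  Xv <- ad_value(X); rv <- ad_value(r)
  val <- Xv + matrix(rv, nrow(Xv), ncol(Xv), byrow = TRUE)
  .ad_op(list(X, r), val,
         function(g) list(g, matrix(colSums(g), 1)))
}

# X (n x m) + column vector c (n x 1), broadcast across columns
ad_add_colvec <- function(X, cc) {
  Xv <- ad_value(X); cv <- as.vector(ad_value(cc))
  .ad_op(list(X, cc), Xv + cv,
         function(g) list(g, matrix(rowSums(g), ncol = 1)))
}

ad_mul_rowvec <- function(X, r) {
  Xv <- ad_value(X); rv <- ad_value(r)
  R <- matrix(rv, nrow(Xv), ncol(Xv), byrow = TRUE)
  .ad_op(list(X, r), Xv * R,
         function(g) list(g * R, matrix(colSums(g * Xv), 1)))
}

ad_mul_colvec <- function(X, cc) {
  Xv <- ad_value(X); cv <- as.vector(ad_value(cc))
  .ad_op(list(X, cc), Xv * cv,
         function(g) list(g * cv, matrix(rowSums(g * Xv), ncol = 1)))
}

# multiply a matrix node by a 1x1 scalar node
ad_scale_node <- function(X, s) {
  Xv <- ad_value(X); sv <- ad_value(s)[1, 1]
  .ad_op(list(X, s), Xv * sv,
         function(g) list(g * sv, matrix(sum(g * Xv), 1, 1)))
}

ad_div <- function(a, b) ad_mul(a, ad_pow(b, -1))

## ---- nonlinearities ----

ad_leakyrelu <- function(a, slope = 0.2) {
  av <- ad_value(a)
  pos <- av > 0
  fac <- ifelse(pos, 1, slope)
  .ad_op(list(a), av * fac, function(g) list(g * fac))
}

ad_relu <- function(a) ad_leakyrelu(a, 0)

ad_elu <- function(a) {
  av <- ad_value(a)
  pos <- av > 0
  val <- ifelse(pos, av, exp(av) - 1)
  fac <- ifelse(pos, 1, val + 1)  # d/dx (e^x - 1) = e^x = val + 1
  .ad_op(list(a), val, function(g) list(g * fac))
}

# row-wise softmax; optional logical mask (TRUE = admissible entry),
# masked-out entries get probability exactly 0
ad_softmax_rows <- function(X, mask = NULL) {
  Xv <- ad_value(X)
  W <- Xv
  if (!is.null(mask)) W[!mask] <- -Inf
  mx <- W[cbind(seq_len(nrow(W)), max.col(W, ties.method = "first"))]
  E <- exp(W - mx)
  if (!is.null(mask)) E[!mask] <- 0
  P <- E / rowSums(E)
  .ad_op(list(X), P, function(g) {
    gs <- rowSums(g * P)
    list(P * (g - gs))
  })
}

# c1 1^T + 1 c2^T for column vectors c1, c2 (n x 1) -> n x n
ad_outer_sum <- function(c1, c2) {
  v1 <- as.vector(ad_value(c1)); v2 <- as.vector(ad_value(c2))
  n1 <- length(v1); n2 <- length(v2)
  val <- matrix(v1, n1, n2) + matrix(v2, n1, n2, byrow = TRUE)
  .ad_op(list(c1, c2), val, function(g) {
    list(matrix(rowSums(g), ncol = 1), matrix(colSums(g), ncol = 1))
  })
}

ad_rbind2 <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  na <- nrow(av)
  .ad_op(list(a, b), rbind(av, bv), function(g) {
    list(g[seq_len(na), , drop = FALSE],
         g[-seq_len(na), , drop = FALSE])
  })
}

ad_cbind2 <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  na <- ncol(av)
  .ad_op(list(a, b), cbind(av, bv), function(g) {
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE])
  })
}

ad_cbind_list <- function(lst) Reduce(ad_cbind2, lst)

# select rows (idx must not repeat)
ad_rows <- function(a, idx) {
  av <- ad_value(a)
  .ad_op(list(a), av[idx, , drop = FALSE], function(g) {
    Z <- matrix(0, nrow(av), ncol(av))
    Z[idx, ] <- g
    list(Z)
  })
}

# row-wise layer normalization with gain/bias parameters (1 x d nodes)
ad_layernorm_rows <- function(X, gamma, beta, eps = 1e-5) {
  d <- ncol(ad_value(X))
  ones_d <- matrix(1 / d, d, 1)
  tape <- X$tape
  m <- ad_matmul(X, ad_const(tape, ones_d))          # n x 1 row means
  Xc <- ad_add_colvec(X, ad_scale(m, -1))
  v <- ad_matmul(ad_mul(Xc, Xc), ad_const(tape, ones_d))
  inv_sd <- ad_pow(ad_addc(v, eps), -0.5)
  Xn <- ad_mul_colvec(Xc, inv_sd)
  ad_add_rowvec(ad_mul_rowvec(Xn, gamma), beta)
}

#' Reverse sweep over an autodiff tape
#'
#' Seeds the given output nodes and walks the tape once in reverse
#' creation order, accumulating gradients onto every reached node
#' (read them back with [ad_grad()], typically on parameter leaves).
#' Each tape is meant for a single forward/backward cycle; build a
#' fresh tape per step.
#'
#' @param outputs an `ad` node or list of them
#' @param seeds matrix (or list of matrices) conformable with each
#'   output's value; for scalar outputs a 1x1 matrix
#' @return Invisibly, the tape.
#' @keywords internal
#' @export
ad_backward <- function(outputs, seeds) {
  if (inherits(outputs, "ad")) outputs <- list(outputs)
  if (!is.list(seeds)) seeds <- list(seeds)
  tape <- outputs[[1]]$tape
  for (k in seq_along(outputs)) {
    node <- outputs[[k]]
    g0 <- .as_mat(seeds[[k]])
    node$grad <- if (is.null(node$grad)) g0 else node$grad + g0
  }
  cur <- tape$last
  while (!is.null(cur)) {
    g <- cur$grad
    if (!is.null(g) && !is.null(cur$bw)) {
      pg <- cur$bw(g)
      ps <- cur$parents
      for (k in seq_along(ps)) {
        p <- ps[[k]]
        if (!p$ng) next
        gk <- pg[[k]]
        if (is.null(gk)) next
        p$grad <- if (is.null(p$grad)) gk else p$grad + gk
      }
    }
    cur <- cur$prev
  }
  invisible(tape)
}
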