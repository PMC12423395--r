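# Shared fixtures and independent oracles. Oracles are deliberately
# naive (double loops, brute-force enumeration) and never reuse the
# package's implementation paths.

fx_surv <- function(n, seed = 1, censor = 0.3, tie_prob = 0) {
  set.seed(seed)
  tm <- round(rexp(n, 0.05), 3) + 0.01
  if (tie_prob > 0) {
    dup <- runif(n) < tie_prob
    tm[dup] <- sample(tm, sum(dup), replace = TRUE)
  }
  survival_table(sprintf("p%03d", seq_len(n)), tm,
                 as.integer(runif(n) > censor))
}

fx_expr <- function(values, modality = "bulk", gene_prefix = "g",
                    unit_prefix = "u") {
  expression_matrix(values,
                    paste0(gene_prefix, seq_len(nrow(values))),
                    paste0(unit_prefix, seq_len(ncol(values))),
                    modality)
}

# random connected-ish sample graph with self-consistent fields
fx_graph <- function(n, p = 0.4, seed = 1, sample_id = "s1",
                     genes = sprintf("g%02d", seq_len(n))) {
  set.seed(seed)
  adj <- matrix(0L, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  }
  feat <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(genes, c("bulk_z", "sc_mean", "sc_detect")))
  structure(list(sample_id = sample_id, nodes = genes,
                 features = feat, adj = adj),
            class = "sample_graph")
}

fx_small_config <- function() {
  gnn_config(hidden = 8, gat_heads = 2, K = 3, d_model = 8,
             tf_heads = 2, tf_layers = 2, d_ff = 16, pe_dim = 2)
}

# fabricate a minimal attention record as gnn_forward would emit
fx_record <- function(sample_id, nodes, attmats) {
  structure(list(sample_id = sample_id, nodes = nodes,
                 attention = attmats),
            class = "gnn_output")
}

# adjusted Rand index between two labelings (pair-counting form)
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  np <- choose(sum(tab), 2)
  exp_ <- si * sj / np
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

## ---- oracles ----

# naive double-loop Cox partial likelihood (Breslow risk sets)
oracle_cox_loss <- function(theta, time, event) {
  loss <- 0
  for (i in seq_along(theta)) {
    if (event[i] != 1) next
    denom <- 0
    for (j in seq_along(theta)) {
      if (time[j] >= time[i]) denom <- denom + exp(theta[j])
    }
    loss <- loss - (theta[i] - log(denom))
  }
  loss
}

# exhaustive pair enumeration for Harrell's C
oracle_cindex <- function(scores, time, event) {
  conc <- disc <- ties <- 0
  n <- length(scores)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    # i must be the confirmed earlier failure
    if (event[i] != 1) next
    comparable <- (time[j] > time[i]) || (time[j] == time[i] && event[j] == 0)
    if (!comparable) next
    if (scores[i] > scores[j]) conc <- conc + 1
    else if (scores[i] < scores[j]) disc <- disc + 1
    else ties <- ties + 1
  }
  total <- conc + disc + ties
  list(cindex = (conc + 0.5 * ties) / total, comparable = total)
}

# brute-force Spearman: Pearson of average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# grid-search maximizer of the single-covariate partial likelihood
# (coarse pass then fine pass; still exhaustive within each grid)
oracle_cox_coef_grid <- function(x, time, event, lo = -3, hi = 3) {
  best <- function(grid) {
    ll <- vapply(grid, function(b) -oracle_cox_loss(b * x, time, event),
                 numeric(1))
    grid[which.max(ll)]
  }
  b0 <- best(seq(lo, hi, by = 0.01))
  best(seq(b0 - 0.02, b0 + 0.02, by = 1e-4))
}

# naive standardized log-rank z for group `hi` (plain loops)
oracle_logrank_z <- function(time, event, hi) {
  O1 <- E1 <- V <- 0
  for (tk in sort(unique(time[event == 1]))) {
    n <- sum(time >= tk)
    n1 <- sum(time >= tk & hi)
    dk <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & hi)
    O1 <- O1 + d1
    E1 <- E1 + dk * n1 / n
    if (n > 1) V <- V + dk * (n1 / n) * (1 - n1 / n) * (n - dk) / (n - 1)
  }
  if (V <= 0) 0 else (O1 - E1) / sqrt(V)
}

# exhaustive admissible-cut scan for the maximally selected statistic
oracle_cutpoint <- function(scores, surv, minprop = 0.1) {
  us <- sort(unique(scores))
  cuts <- (us[-length(us)] + us[-1]) / 2
  minn <- max(1, ceiling(minprop * length(scores)))
  best <- NULL
  for (ct in cuts) {
    hi <- scores > ct
    if (sum(hi) < minn || sum(!hi) < minn) next
    if (length(unique(hi)) < 2) next
    z <- oracle_logrank_z(surv$time, surv$event, hi)
    if (is.null(best) || abs(z) > best$stat + 1e-12)
      best <- list(cut = ct, stat = abs(z))
  }
  best
}
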