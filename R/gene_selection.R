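# Per-sample key-gene selection: univariate Cox screening on the bulk
# cohort, Spearman similarity between single cells and bulk samples,
# and a signed significance score combining correlation direction with
# FDR that picks each sample's graph nodes.

# column-wise average ranks
.rank_cols <- function(m) apply(m, 2, rank, ties.method = "average")

# Spearman rho p-value via the t approximation (average ranks for ties)
.spearman_p <- function(rho, n) {
  rho <- pmin(1, pmax(-1, rho))
  p <- rep(1, length(rho))
  ok <- is.finite(rho) & n > 2 & abs(rho) < 1
  tt <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[is.finite(rho) & abs(rho) >= 1 & n > 2] <- 0
  p
}

#' Univariate Cox screen of prognostic genes
#'
#' Fits one single-covariate Cox model per gene on the bulk cohort and
#' keeps genes whose Wald p-value falls below `alpha`. Genes with
#' constant expression carry no information and are reported with
#' coefficient 0 and p-value 1; non-converged fits are flagged and
#' excluded from the prognostic set.
#'
#' @param bulk a bulk [expression_matrix()]
#' @param surv a [survival_table()] covering all bulk samples
#' @param alpha significance threshold for the prognostic set (default
#'   0.05)
#' @return A list of class `cox_screen`: `table` (data frame with
#'   gene_id, coef, hr, se, wald_p, flagged) and `prognostic_genes`.
#' @export
univariate_cox_screen <- function(bulk, surv, alpha = 0.05) {
  idx <- match(bulk$unit_ids, surv$sample_id)
  if (anyNA(idx))
    stop("input error: bulk samples missing from survival table: ",
         paste(utils::head(bulk$unit_ids[is.na(idx)], 3), collapse = ", "))
  sv <- surv[idx, ]
  if (sum(sv$event) < 2) stop("estimation error: fewer than two events")
  g <- bulk$gene_ids
  coef <- se <- pv <- rep(NA_real_, length(g))
  flagged <- logical(length(g))
  for (k in seq_along(g)) {
    fit <- tryCatch(cox_fit(bulk$values[k, ], sv),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged || !is.finite(fit$coef[1])) {
      flagged[k] <- TRUE
      pv[k] <- 1
      next
    }
    coef[k] <- fit$coef[1]
    se[k] <- fit$se[1]
    pv[k] <- fit$wald_p[1]
    flagged[k] <- fit$flagged[1]
  }
  coef[flagged & is.na(coef)] <- NA_real_
  tab <- data.frame(gene_id = g, coef = coef, hr = exp(coef), se = se,
                    wald_p = pv, flagged = flagged,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 prognostic_genes = g[!flagged & !is.na(pv) & pv < alpha],
                 alpha = alpha),
            class = "cox_screen")
}

#' Spearman similarity between single cells and bulk samples
#'
#' For every (cell, sample) pair, the Spearman rank correlation between
#' the cell's and the sample's expression profiles over `gene_subset`
#' (normally the survival-screened prognostic genes). P-values use the
#' t approximation with average ranks for ties. A cell or sample that
#' is constant over the subset yields rho 0 / p 1 and is flagged.
#'
#' @param aligned an [align_genes()] result
#' @param gene_subset genes to correlate over (>= 3, subset of
#'   `shared_genes`)
#' @return A list of class `cell_sample_similarity`: `rho` and `pval`
#'   (cells x samples), `fdr` (BH over all cells x samples),
#'   `flagged_cells`, `flagged_samples`.
#' @export
cell_sample_similarity <- function(aligned, gene_subset) {
  stopifnot(inherits(aligned, "aligned_multimodal"))
  if (length(gene_subset) < 3)
    stop("input error: need at least 3 genes to correlate over")
  if (!all(gene_subset %in% aligned$shared_genes))
    stop("input error: gene_subset must be drawn from shared_genes")
  scv <- aligned$sc$values[gene_subset, , drop = FALSE]
  bkv <- aligned$bulk$values[gene_subset, , drop = FALSE]
  ng <- length(gene_subset)
  rs <- .rank_cols(scv)
  rb <- .rank_cols(bkv)
  const_cell <- apply(scv, 2, function(x) length(unique(x)) == 1)
  const_samp <- apply(bkv, 2, function(x) length(unique(x)) == 1)
  rho <- suppressWarnings(stats::cor(rs, rb))
  rho[const_cell, ] <- 0
  rho[, const_samp] <- 0
  rho[!is.finite(rho)] <- 0
  pval <- matrix(.spearman_p(rho, ng), nrow(rho), ncol(rho))
  pval[const_cell, ] <- 1
  pval[, const_samp] <- 1
  dimnames(rho) <- dimnames(pval) <-
    list(aligned$sc$unit_ids, aligned$bulk$unit_ids)
  fdr <- matrix(bh_adjust(as.vector(pval)), nrow(pval), ncol(pval),
                dimnames = dimnames(pval))
  structure(list(rho = rho, pval = pval, fdr = fdr,
                 flagged_cells = aligned$sc$unit_ids[const_cell],
                 flagged_samples = aligned$bulk$unit_ids[const_samp]),
            class = "cell_sample_similarity")
}

#' Signed significance score from correlation sign and FDR
#'
#' `1 - 2*fdr` for positive correlations, `2*fdr - 1` for negative
#' ones, so a score of +/-1 marks a perfectly significant positive or
#' negative association. Entries with no evidence -- zero correlation,
#' or FDR above 0.5 (where the raw formula would flip sign and grow
#' again) -- are clamped to 0, so non-informative genes can never pass
#' a selection threshold and `|score| > tau` is equivalent to
#' `fdr < (1 - tau)/2`.
#'
#' @param rho correlation value(s)
#' @param fdr adjusted p-value(s), same shape
#' @return Scores in \[-1, 1\] with `sign(score) == sign(rho)` wherever
#'   the score is nonzero.
#' @export
corgene_score <- function(rho, fdr) {
  s <- sign(rho) * pmax(0, 1 - 2 * fdr)
  s[rho == 0] <- 0
  s
}

#' Per-sample gene association scores
#'
#' Bridges cell-level similarity to per-(gene, sample) scores in two
#' stages: the cell-to-sample similarity provides, for each sample, a
#' vector over cells measuring how much each cell resembles that
#' sample; each gene's single-cell expression is then Spearman-
#' correlated against that vector. Genes whose expression tracks the
#' cells that resemble a sample are that sample's candidates. P-values
#' are BH-adjusted within each sample (across genes) and combined with
#' the correlation sign by [corgene_score()].
#'
#' @param aligned an [align_genes()] result
#' @param sim a [cell_sample_similarity()] computed on `aligned`
#' @param gene_subset candidate genes (rows of the score table)
#' @return A list of class `corgene_table`: matrices `score`, `fdr`,
#'   `pval`, `rho_gene` (genes x samples).
#' @export
corgene_table <- function(aligned, sim, gene_subset) {
  stopifnot(inherits(sim, "cell_sample_similarity"))
  if (!all(gene_subset %in% aligned$shared_genes))
    stop("input error: gene_subset must be drawn from shared_genes")
  scv <- aligned$sc$values[gene_subset, , drop = FALSE]
  n_cells <- ncol(scv)
  # rank each gene's expression across cells once; Pearson on ranks
  # equals Spearman with average ranks
  gr <- t(apply(scv, 1, rank, ties.method = "average"))  # genes x cells
  const_gene <- apply(scv, 1, function(x) length(unique(x)) == 1)
  samples <- colnames(sim$rho)
  rho_gene <- matrix(0, length(gene_subset), length(samples),
                     dimnames = list(gene_subset, samples))
  for (s in seq_along(samples)) {
    v <- rank(sim$rho[, s], ties.method = "average")
    r <- suppressWarnings(stats::cor(t(gr), v))
    r[!is.finite(r)] <- 0
    rho_gene[, s] <- r
  }
  rho_gene[const_gene, ] <- 0
  pval <- matrix(.spearman_p(rho_gene, n_cells),
                 nrow(rho_gene), ncol(rho_gene),
                 dimnames = dimnames(rho_gene))
  pval[const_gene, ] <- 1
  fdr <- apply(pval, 2, bh_adjust)
  dimnames(fdr) <- dimnames(pval)
  score <- corgene_score(rho_gene, fdr)
  structure(list(score = score, fdr = fdr, pval = pval,
                 rho_gene = rho_gene),
            class = "corgene_table")
}

#' Select per-sample key genes
#'
#' A gene is a key gene for a sample when its absolute score strictly
#' exceeds `tau` (default 0.995) and its FDR is strictly below `q`
#' (default 0.05). When fewer than `min_genes` pass for a sample, the
#' top `min_genes` genes by absolute score are taken instead and the
#' sample is flagged. `max_genes` caps each list (ranked by absolute
#' score) so per-sample graphs stay at a tractable size.
#'
#' @param table a [corgene_table()]
#' @param tau score threshold (strict >)
#' @param q FDR threshold (strict <)
#' @param min_genes fallback lower bound per sample
#' @param max_genes upper cap per sample (`Inf` to disable)
#' @return A list of class `key_gene_set`: `genes` (named list,
#'   sample -> ordered gene ids), `fallback_samples`.
#' @export
select_key_genes <- function(table, tau = 0.995, q = 0.05,
                             min_genes = 20, max_genes = 100) {
  stopifnot(inherits(table, "corgene_table"))
  n_cand <- nrow(table$score)
  if (min_genes > n_cand)
    stop("config error: min_genes (", min_genes,
         ") exceeds candidate genes (", n_cand, ")")
  samples <- colnames(table$score)
  out <- vector("list", length(samples))
  names(out) <- samples
  fell_back <- character(0)
  for (s in samples) {
    sc <- table$score[, s]
    ok <- abs(sc) > tau & table$fdr[, s] < q
    genes <- rownames(table$score)[ok]
    if (length(genes) < min_genes) {
      fell_back <- c(fell_back, s)
      genes <- rownames(table$score)[order(-abs(sc))][seq_len(min_genes)]
    }
    genes <- genes[order(-abs(sc[genes]))]
    if (length(genes) > max_genes) genes <- genes[seq_len(max_genes)]
    out[[s]] <- genes
  }
  if (length(fell_back))
    message("key-gene fallback (top-", min_genes, " by |score|) for ",
            length(fell_back), " sample(s)")
  structure(list(genes = out, fallback_samples = fell_back,
                 tau = tau, q = q),
            class = "key_gene_set")
}
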