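# Gene-graph construction: embed genes per modality, connect k-nearest
# neighbours into binary adjacencies, fuse the two modalities by
# logical OR, and induce per-sample graphs on each sample's key genes.

#' Embed genes as points in a low-dimensional space
#'
#' Each gene is a point whose features are its expression across units
#' (cells for the single-cell modality, samples for bulk), z-scored per
#' gene first. The deterministic PCA backend projects onto the leading
#' principal components with a fixed sign convention (largest-magnitude
#' loading positive), so identical inputs give identical embeddings.
#'
#' @param expr an [expression_matrix()]
#' @param genes genes to embed (rows of the embedding)
#' @param method embedding backend; `"pca"` is the deterministic
#'   default. `"umap"` is accepted for interface compatibility but no
#'   UMAP backend ships with this package.
#' @param dims embedding dimension (>= 2, < number of genes)
#' @param seed unused by the PCA backend; kept so callers can fix one
#'   uniformly
#' @return genes x dims numeric matrix with gene ids as row names.
#' @export
embed_genes <- function(expr, genes, method = c("pca", "umap"),
                        dims = 10, seed = 1) {
  method <- match.arg(method)
  if (method == "umap")
    stop("config error: no UMAP backend is available; use method = 'pca'")
  if (dims < 2) stop("config error: dims must be >= 2")
  if (length(genes) <= dims)
    stop("config error: need more genes (", length(genes),
         ") than embedding dims (", dims, ")")
  missing <- setdiff(genes, expr$gene_ids)
  if (length(missing))
    stop("input error: genes absent from expression matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  X <- expr$values[genes, , drop = FALSE]
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  X <- (X - mu) / ifelse(sdv > 0, sdv, 1)
  X[sdv == 0, ] <- 0
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(dims, ncol(pc$x))
  emb <- matrix(0, length(genes), dims,
                dimnames = list(genes, paste0("dim", seq_len(dims))))
  emb[, seq_len(k)] <- pc$x[, seq_len(k), drop = FALSE]
  # sign convention: largest-|.| coordinate of each component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(emb[, j]))
    if (emb[i, j] < 0) emb[, j] <- -emb[, j]
  }
  emb
}

#' k-nearest-neighbour binary adjacency
#'
#' Directed kNN by Euclidean distance (self excluded), symmetrized by
#' OR. Distance ties are broken by lexicographic gene id so the graph
#' is reproducible.
#'
#' @param emb genes x dims embedding with gene ids as row names
#' @param k neighbours per gene (1 <= k < genes)
#' @param modality tag carried on the result
#' @return A list of class `modality_adjacency`: `genes`, `adj`
#'   (binary, symmetric, zero diagonal), `modality`.
#' @export
knn_adjacency <- function(emb, k = 15, modality = c("bulk", "single_cell")) {
  modality <- match.arg(modality)
  n <- nrow(emb)
  if (k < 1 || k >= n)
    stop("config error: k must satisfy 1 <= k < number of genes (", n, ")")
  ids <- rownames(emb)
  d <- as.matrix(stats::dist(emb))
  adj <- matrix(0L, n, n, dimnames = list(ids, ids))
  lex <- order(ids)  # rank of each index in lexicographic id order
  lexrank <- match(seq_len(n), lex)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    o <- cand[order(d[i, cand], lexrank[cand])]
    nb <- o[seq_len(k)]
    adj[i, nb] <- 1L
  }
  adj <- 1L * ((adj + t(adj)) > 0)
  diag(adj) <- 0L
  structure(list(genes = ids, adj = adj, modality = modality),
            class = "modality_adjacency")
}

#' Fuse single-cell and bulk adjacencies
#'
#' Element-wise sum followed by binarization: a gene pair connected in
#' either modality stays connected in the fused graph.
#'
#' @param a_sc,a_bulk [knn_adjacency()] results on identical gene lists
#' @return A list of class `fused_adjacency`: `genes`, `adj`.
#' @export
fuse_adjacency <- function(a_sc, a_bulk) {
  if (!identical(a_sc$genes, a_bulk$genes))
    stop("alignment error: adjacency gene lists differ")
  adj <- 1L * ((a_sc$adj + a_bulk$adj) > 0)
  diag(adj) <- 0L
  structure(list(genes = a_sc$genes, adj = adj), class = "fused_adjacency")
}

#' Build one sample's gene graph
#'
#' Nodes are the sample's key genes; the adjacency is the induced
#' submatrix of the fused gene graph. Node features (F = 3 per node)
#' are: the gene's bulk expression in this sample z-scored across
#' samples, its mean single-cell expression, and the fraction of cells
#' expressing it (nonzero).
#'
#' @param sample_id bulk sample id
#' @param key_genes this sample's key genes (subset of `fused$genes`)
#' @param fused a [fuse_adjacency()] result
#' @param bulk bulk [expression_matrix()] containing `sample_id`
#' @param sc single-cell [expression_matrix()]
#' @return A list of class `sample_graph`: `sample_id`, `nodes`,
#'   `features` (nodes x 3), `adj`.
#' @export
build_sample_graph <- function(sample_id, key_genes, fused, bulk, sc) {
  missing <- setdiff(key_genes, fused$genes)
  if (length(missing))
    stop("input error: key genes absent from fused graph: ",
         paste(utils::head(missing, 3), collapse = ", "))
  if (!sample_id %in% bulk$unit_ids)
    stop("input error: sample '", sample_id, "' not in bulk matrix")
  adj <- fused$adj[key_genes, key_genes, drop = FALSE]
  bv <- bulk$values[key_genes, , drop = FALSE]
  mu <- rowMeans(bv)
  sdv <- apply(bv, 1, stats::sd)
  z <- (bv[, sample_id] - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0] <- 0
  scv <- sc$values[key_genes, , drop = FALSE]
  feat <- cbind(bulk_z = z,
                sc_mean = rowMeans(scv),
                sc_detect = rowMeans(scv != 0))
  rownames(feat) <- key_genes
  if (sum(adj) == 0)
    warning("sample '", sample_id,
            "' graph has no edges; self-loops will carry the attention")
  structure(list(sample_id = sample_id, nodes = key_genes,
                 features = feat, adj = adj),
            class = "sample_graph")
}

#' Export an adjacency as a two-column edge list
#' @param adj binary symmetric matrix with gene-id dimnames
#' @return data frame with columns `gene_a`, `gene_b` (a < b).
#' @export
adjacency_edges <- function(adj) {
  idx <- which(adj > 0 & upper.tri(adj), arr.ind = TRUE)
  data.frame(gene_a = rownames(adj)[idx[, 1]],
             gene_b = colnames(adj)[idx[, 2]],
             stringsAsFactors = FALSE)
}
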