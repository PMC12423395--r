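# Expression-matrix and survival-table containers plus readers/writers.
# CSV/TSV layout: genes in rows, first column holds the gene id, header
# row holds the unit (cell or sample) ids. MTX input is a MatrixMarket
# triplet with two one-column sidecar files for gene and unit ids.

#' Construct an expression matrix
#'
#' A light container for a genes x units matrix of normalized log-scale
#' expression, with a modality tag distinguishing single-cell from bulk
#' data. Values must be finite and ids unique.
#'
#' @param values numeric matrix, genes in rows, units (cells or samples)
#'   in columns
#' @param gene_ids character vector of unique gene identifiers
#' @param unit_ids character vector of unique cell/sample identifiers
#' @param modality `"single_cell"` or `"bulk"`
#' @return An object of class `expr_matrix` with fields `values`,
#'   `gene_ids`, `unit_ids`, `modality`.
#' @export
expression_matrix <- function(values, gene_ids, unit_ids,
                              modality = c("bulk", "single_cell")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  unit_ids <- as.character(unit_ids)
  if (nrow(values) != length(gene_ids))
    stop("validation error: ", length(gene_ids), " gene ids for ",
         nrow(values), " rows")
  if (ncol(values) != length(unit_ids))
    stop("validation error: ", length(unit_ids), " unit ids for ",
         ncol(values), " columns")
  if (anyDuplicated(gene_ids))
    stop("validation error: duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(unit_ids))
    stop("validation error: duplicate unit ids: ",
         paste(unique(unit_ids[duplicated(unit_ids)]), collapse = ", "))
  bad <- which(!is.finite(values))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(values))
    stop("validation error: non-finite value at gene '", gene_ids[rc[1]],
         "' (row ", rc[1], "), unit '", unit_ids[rc[2]], "' (col ", rc[2],
         ")", if (length(bad) > 1) paste0(" and ", length(bad) - 1, " more"))
  }
  dimnames(values) <- list(gene_ids, unit_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 unit_ids = unit_ids, modality = modality),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", length(x$gene_ids), " genes x ",
      length(x$unit_ids), " ", x$modality, " units\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Construct a survival table
#'
#' @param sample_ids unique sample identifiers
#' @param time positive follow-up times in months
#' @param event event indicator: 1 = event observed (death/progression),
#'   0 = censored
#' @return A data frame of class `surv_table` with columns `sample_id`,
#'   `time`, `event`.
#' @export
survival_table <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  time <- as.double(time)
  event <- as.integer(event)
  if (anyDuplicated(sample_ids))
    stop("validation error: duplicate sample ids")
  if (length(time) != length(sample_ids) || length(event) != length(sample_ids))
    stop("validation error: column lengths differ")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("validation error: follow-up times must be positive and finite")
  if (!all(event %in% c(0L, 1L)))
    stop("validation error: event indicator must be 0 or 1")
  structure(data.frame(sample_id = sample_ids, time = time, event = event,
                       stringsAsFactors = FALSE),
            class = c("surv_table", "data.frame"))
}

#' Read an expression matrix from disk
#'
#' @param path file path; for `format = "mtx"` the MatrixMarket file,
#'   with gene and unit id sidecars (one id per line) found either via
#'   `gene_path`/`unit_path` or at `<path>.genes` / `<path>.units`
#' @param format `"csv"`, `"tsv"` or `"mtx"`
#' @param modality `"bulk"` or `"single_cell"`
#' @param gene_path,unit_path optional sidecar paths for mtx input
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("csv", "tsv", "mtx"),
                            modality = c("bulk", "single_cell"),
                            gene_path = NULL, unit_path = NULL) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("input error: file not found: ", path)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "")
    gene_ids <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    expression_matrix(vals, gene_ids, colnames(df)[-1], modality)
  } else {
    gp <- gene_path %||% paste0(path, ".genes")
    up <- unit_path %||% paste0(path, ".units")
    if (!file.exists(gp)) stop("input error: gene id sidecar not found: ", gp)
    if (!file.exists(up)) stop("input error: unit id sidecar not found: ", up)
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(gp)
    unit_ids <- readLines(up)
    expression_matrix(m, gene_ids, unit_ids, modality)
  }
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]: values round-trip through csv and mtx
#' to within 1e-9.
#'
#' @param expr an [expression_matrix()]
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(expr, "expr_matrix"))
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene_id = expr$gene_ids, expr$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene_id", expr$unit_ids)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(expr$values, sparse = TRUE), path)
    writeLines(expr$gene_ids, paste0(path, ".genes"))
    writeLines(expr$unit_ids, paste0(path, ".units"))
  }
  invisible(path)
}

#' Read a survival table (CSV with columns sample_id, time, event)
#' @param path file path
#' @return A [survival_table()].
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("validation error: survival file must have columns ",
         paste(need, collapse = ", "))
  survival_table(df$sample_id, df$time, df$event)
}

#' @rdname read_survival
#' @param surv a [survival_table()]
#' @export
write_survival <- function(surv, path) {
  utils::write.csv(as.data.frame(surv), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align single-cell and bulk matrices on a shared gene universe
#'
#' Both matrices are subset and reordered to the lexicographically
#' sorted intersection of their gene ids, so downstream graphs are
#' reproducible regardless of input file order. Matching is exact
#' string match; identifier conversion is an external concern.
#'
#' @param sc single-cell [expression_matrix()]
#' @param bulk bulk [expression_matrix()]
#' @return A list of class `aligned_multimodal` with fields `sc`,
#'   `bulk`, `shared_genes`.
#' @export
align_genes <- function(sc, bulk) {
  stopifnot(inherits(sc, "expr_matrix"), inherits(bulk, "expr_matrix"))
  shared <- sort(intersect(sc$gene_ids, bulk$gene_ids))
  if (length(shared) == 0)
    stop("alignment error: no genes shared between modalities")
  sub <- function(e) expression_matrix(e$values[shared, , drop = FALSE],
                                       shared, e$unit_ids, e$modality)
  structure(list(sc = sub(sc), bulk = sub(bulk), shared_genes = shared),
            class = "aligned_multimodal")
}

#' @export
print.aligned_multimodal <- function(x, ...) {
  cat("<aligned_multimodal> ", length(x$shared_genes), " shared genes; ",
      length(x$sc$unit_ids), " cells, ", length(x$bulk$unit_ids),
      " samples\n", sep = "")
  invisible(x)
}

#' Minimal expression normalization
#'
#' `log1p_scale` rescales each unit's total to `target_total` (the
#' common per-cell library-size convention) then applies `log(1 + x)`;
#' `zscore_genes` centres and scales each gene row (constant rows map
#' to zero); `none` returns the input unchanged. Heavier normalization
#' (Seurat, RMA, ComBat) is expected to happen upstream.
#'
#' @param expr an [expression_matrix()]
#' @param method one of `"log1p_scale"`, `"zscore_genes"`, `"none"`
#' @param target_total per-unit total for `log1p_scale` (default 1e4)
#' @return A normalized [expression_matrix()].
#' @export
normalize_expression <- function(expr,
                                 method = c("log1p_scale", "zscore_genes", "none"),
                                 target_total = 1e4) {
  if (length(method) == 1 &&
      !method %in% c("log1p_scale", "zscore_genes", "none"))
    stop("config error: unknown normalization method '", method, "'")
  method <- match.arg(method)
  v <- expr$values
  if (method == "none") return(expr)
  if (method == "log1p_scale") {
    tot <- colSums(v)
    tot[tot == 0] <- 1  # empty units stay zero rather than dividing by 0
    v <- log1p(sweep(v, 2, tot / target_total, "/"))
  } else {
    mu <- rowMeans(v)
    sdv <- apply(v, 1, stats::sd)
    v <- (v - mu) / ifelse(sdv > 0, sdv, 1)
    v[sdv == 0, ] <- 0
  }
  expression_matrix(v, expr$gene_ids, expr$unit_ids, expr$modality)
}

#' Truncate follow-up at a horizon
#'
#' Samples followed beyond `horizon` months are administratively
#' censored there: time is set to the horizon and the event indicator
#' to 0. Rows at or below the horizon are unchanged. Used to put
#' cohorts with different follow-up on a common footing (e.g. 60- or
#' 36-month horizons).
#'
#' @param surv a [survival_table()]
#' @param horizon positive horizon in months
#' @return A truncated [survival_table()].
#' @export
truncate_followup <- function(surv, horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1 || !is.finite(horizon) ||
      horizon <= 0)
    stop("config error: horizon must be a positive number")
  over <- surv$time > horizon
  out <- surv
  out$time[over] <- horizon
  out$event[over] <- 0L
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
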