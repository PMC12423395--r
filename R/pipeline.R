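# End-to-end orchestration: gene selection -> graph construction ->
# training -> risk scoring -> cutpoint stratification -> attention
# interpretability, with artifacts written as TSV/JSON for downstream
# inspection.

.pipeline_stages <- c("select", "graph", "train", "predict",
                      "cutpoint", "interpret")

.stage_deps <- list(select = character(0), graph = "select",
                    train = "graph", predict = "train",
                    cutpoint = "predict", interpret = "cutpoint")

#' Run the analysis pipeline
#'
#' Executes the requested stages in order on a paired single-cell /
#' bulk cohort. Each stage stores its results in the returned state
#' and (when `outdir` is given) writes TSV artifacts plus a JSON
#' manifest with the configuration echo, seed and per-stage wall
#' times. A stage whose upstream results are missing raises an error
#' naming the stage to run first; passing a previous `state` resumes a
#' partial run.
#'
#' @param sc single-cell [expression_matrix()]
#' @param bulk bulk [expression_matrix()]
#' @param surv a [survival_table()]
#' @param outdir artifact directory (`NULL` to skip writing)
#' @param stages subset of `select`, `graph`, `train`, `predict`,
#'   `cutpoint`, `interpret`
#' @param alpha univariate Cox screening threshold
#' @param tau,q,min_genes,max_genes key-gene selection controls
#'   (see [select_key_genes()])
#' @param embed_dims,k gene embedding dimension and kNN degree
#' @param model_config a [gnn_config()]
#' @param train_cfg a [train_config()]
#' @param horizon optional follow-up truncation in months
#' @param minprop minimum group proportion for the cutpoint
#' @param train_ids optional sample ids to train on (risk scores are
#'   still produced for every sample)
#' @param seed seed forwarded to embedding/training/interpretation
#' @param state a previous `run_pipeline` result to resume from
#' @return A list of class `pipeline_state` holding every computed
#'   object (`screen`, `key_genes`, `fused`, `graphs`, `model`,
#'   `risk_scores`, `cutpoint`, `node_stats`, `edge_stats`, `modules`,
#'   `manifest`).
#' @export
run_pipeline <- function(sc, bulk, surv, outdir = NULL,
                         stages = .pipeline_stages,
                         alpha = 0.05, tau = 0.995, q = 0.05,
                         min_genes = 20, max_genes = 100,
                         embed_dims = 10, k = 15,
                         model_config = gnn_config(),
                         train_cfg = train_config(),
                         horizon = NULL, minprop = 0.1,
                         train_ids = NULL, seed = 1, state = NULL) {
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  if (!is.null(outdir) && !dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create ", outdir)
  st <- state %||% structure(list(), class = "pipeline_state")
  if (!is.null(horizon)) surv <- truncate_followup(surv, horizon)
  st$surv <- surv
  timings <- st$manifest$timings %||% list()
  art <- function(name, df) {
    if (!is.null(outdir))
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
  }
  need <- function(stage) {
    dep <- .stage_deps[[stage]]
    for (d in dep) {
      if (is.null(st[[.stage_result[[d]]]]))
        stop("input error: stage '", stage, "' needs results of stage '",
             d, "'; run '", d, "' first")
    }
  }
  for (stage in stages) {
    need(stage)
    t0 <- proc.time()[["elapsed"]]
    if (stage == "select") {
      aligned <- align_genes(sc, bulk)
      screen <- univariate_cox_screen(aligned$bulk, surv, alpha = alpha)
      prog <- screen$prognostic_genes
      if (length(prog) < max(min_genes, embed_dims + 1))
        stop("estimation error: only ", length(prog),
             " prognostic genes at alpha = ", alpha)
      sim <- cell_sample_similarity(aligned, prog)
      cg <- corgene_table(aligned, sim, prog)
      kg <- select_key_genes(cg, tau = tau, q = q,
                             min_genes = min_genes, max_genes = max_genes)
      st$aligned <- aligned; st$screen <- screen; st$similarity <- sim
      st$corgene <- cg; st$key_genes <- kg
      art("cox_screen.tsv", screen$table)
      art("key_genes.tsv",
          data.frame(sample_id = names(kg$genes),
                     genes = vapply(kg$genes, paste, "", collapse = ",")))
    } else if (stage == "graph") {
      prog <- st$screen$prognostic_genes
      emb_sc <- embed_genes(st$aligned$sc, prog, "pca", embed_dims, seed)
      emb_bk <- embed_genes(st$aligned$bulk, prog, "pca", embed_dims, seed)
      k_eff <- min(k, length(prog) - 1)  # small gene universes
      fused <- fuse_adjacency(knn_adjacency(emb_sc, k_eff, "single_cell"),
                              knn_adjacency(emb_bk, k_eff, "bulk"))
      graphs <- lapply(names(st$key_genes$genes), function(s)
        build_sample_graph(s, st$key_genes$genes[[s]], fused,
                           st$aligned$bulk, st$aligned$sc))
      names(graphs) <- names(st$key_genes$genes)
      st$fused <- fused; st$graphs <- graphs
      art("fused_edges.tsv", adjacency_edges(fused$adj))
    } else if (stage == "train") {
      gtrain <- st$graphs
      if (!is.null(train_ids)) gtrain <- st$graphs[train_ids]
      st$model <- fit_gnn(gtrain, surv, config = train_cfg,
                          model_config = model_config)
      art("history.tsv", st$model$history)
    } else if (stage == "predict") {
      st$risk_scores <- predict_risk(st$model, st$graphs)
      art("risk_scores.tsv",
          data.frame(sample_id = names(st$risk_scores),
                     theta = unname(st$risk_scores)))
    } else if (stage == "cutpoint") {
      cut_ids <- if (!is.null(train_ids)) train_ids else names(st$risk_scores)
      sv <- surv[match(cut_ids, surv$sample_id), ]
      st$cutpoint <- optimal_cutpoint(st$risk_scores[cut_ids], sv,
                                      minprop = minprop)
      st$risk_groups <- factor(
        ifelse(st$risk_scores > st$cutpoint$cutoff, "high", "low"),
        levels = c("low", "high"))
      names(st$risk_groups) <- names(st$risk_scores)
      art("risk_groups.tsv",
          data.frame(sample_id = names(st$risk_scores),
                     theta = unname(st$risk_scores),
                     group = as.character(st$risk_groups)))
    } else if (stage == "interpret") {
      records <- lapply(st$graphs, function(g) gnn_forward(st$model, g))
      agg <- aggregate_attention(records,
                                 as.character(st$risk_groups))
      st$node_stats <- node_analysis(agg)
      st$edge_stats <- edge_analysis(agg, st$node_stats)
      st$modules <- module_analysis(st$edge_stats, st$node_stats,
                                    seed = seed)
      st$attention_aggregate <- agg
      art("nodes.tsv", st$node_stats)
      art("edges.tsv", st$edge_stats)
      art("driver_edges.tsv",
          st$edge_stats[st$edge_stats$is_driver, , drop = FALSE])
      art("modules.tsv", st$modules$modules)
    }
    timings[[stage]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }
  st$manifest <- list(
    package_version = as.character(utils::packageVersion("scgraphsurv")),
    seed = seed, stages = stages, timings = timings,
    params = list(alpha = alpha, tau = tau, q = q, min_genes = min_genes,
                  max_genes = max_genes, embed_dims = embed_dims, k = k,
                  horizon = horizon, minprop = minprop,
                  model_config = unclass(model_config),
                  train_config = unclass(train_cfg)))
  if (!is.null(outdir))
    jsonlite::write_json(st$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  st
}

# which state field marks a stage as done
.stage_result <- list(select = "key_genes", graph = "graphs",
                      train = "model", predict = "risk_scores",
                      cutpoint = "cutpoint", interpret = "node_stats")
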