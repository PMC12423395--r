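# Training: Cox partial-likelihood loss over the full cohort (the risk
# set requires every patient in the batch), the combined objective with
# the MinCut regularizers, Adam with early stopping, risk scoring, and
# maximally selected rank-statistic cutpoints.

#' Cox partial-likelihood loss
#'
#' `-sum_{i in E} (theta_i - log sum_{j in R_i} exp(theta_j))` with the
#' risk set `R_i = {j : T_j >= T_i}` and Breslow handling of tied event
#' times; the inner log-sum is computed with log-sum-exp
#' stabilization. Invariant to adding a constant to all scores.
#'
#' @param theta numeric risk scores
#' @param time positive follow-up times
#' @param event binary event indicators (>= 1 event required)
#' @return The (nonnegative) loss value.
#' @export
cox_partial_loss <- function(theta, time, event) {
  if (sum(event) < 1) stop("estimation error: no events in batch")
  ei <- which(event == 1)
  m <- max(theta)
  loss <- 0
  for (i in ei) {
    risk <- time >= time[i]
    loss <- loss - (theta[i] - (m + log(sum(exp(theta[risk] - m)))))
  }
  loss
}

# analytic gradient of cox_partial_loss wrt theta
.cox_loss_grad <- function(theta, time, event) {
  ei <- which(event == 1)
  m <- max(theta)
  w <- exp(theta - m)
  g <- numeric(length(theta))
  g[ei] <- -1
  for (i in ei) {
    risk <- time >= time[i]
    g[risk] <- g[risk] + w[risk] / sum(w[risk])
  }
  g
}

#' Combined training objective
#'
#' `L = L_Cox + lambda * (l_cut + l_ortho)`, where the pooling terms
#' are the (cohort-averaged) MinCut regularizers.
#'
#' @param cox_loss Cox partial-likelihood loss
#' @param l_cut,l_ortho pooling regularizer values
#' @param lambda nonnegative balance weight
#' @return Scalar objective.
#' @export
total_loss <- function(cox_loss, l_cut, l_ortho, lambda = 1) {
  cox_loss + lambda * (l_cut + l_ortho)
}

#' Training configuration
#'
#' @param lr Adam learning rate
#' @param weight_decay L2 penalty added to gradients
#' @param lambda weight of the pooling regularizers in the objective
#' @param max_epochs epoch cap
#' @param patience consecutive epochs without sufficient improvement
#'   tolerated before stopping
#' @param min_delta loss improvement (vs the best so far) that counts
#'   as progress
#' @param seed RNG seed for parameter initialization
#' @param verbose print per-epoch losses
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 5e-4, lambda = 1,
                         max_epochs = 300, patience = 20, min_delta = 1e-4,
                         seed = 1, verbose = FALSE) {
  stopifnot(patience >= 1, lambda >= 0, lr > 0, min_delta > 0)
  structure(list(lr = lr, weight_decay = weight_decay, lambda = lambda,
                 max_epochs = max_epochs, patience = patience,
                 min_delta = min_delta, seed = seed, verbose = verbose),
            class = "train_config")
}

# early-stopping bookkeeping, kept pure so the contract is testable:
# returns updated state; state$stop signals termination
.early_stop_update <- function(state, loss, min_delta, patience) {
  if (is.null(state$best) || loss < state$best - min_delta) {
    state$best <- loss
    state$counter <- 0L
    state$improved <- TRUE
  } else {
    state$counter <- state$counter + 1L
    state$improved <- FALSE
  }
  state$stop <- state$counter >= patience
  state
}

#' Fit the graph network on a cohort
#'
#' Full-cohort gradient steps (the Cox loss needs the complete risk
#' set), Adam updates, and early stopping once the loss stops
#' improving by `min_delta` for `patience` consecutive epochs. The
#' parameters achieving the best objective are returned.
#'
#' @param graphs list of [build_sample_graph()] objects
#' @param surv a [survival_table()] covering every graph's sample
#' @param config a [train_config()]
#' @param model_config a [gnn_config()]
#' @return A `gnn_model` with extra fields `history` (per-epoch data
#'   frame of cox loss, l_cut, l_ortho, total), `best_epoch`,
#'   `sample_ids`.
#' @export
fit_gnn <- function(graphs, surv, config = train_config(),
                    model_config = gnn_config()) {
  ids <- vapply(graphs, function(g) g$sample_id, character(1))
  idx <- match(ids, surv$sample_id)
  if (anyNA(idx))
    stop("input error: graphs without survival rows: ",
         paste(utils::head(ids[is.na(idx)], 3), collapse = ", "))
  tm <- surv$time[idx]; ev <- surv$event[idx]
  if (sum(ev) < 1) stop("estimation error: no events in cohort")
  n <- length(graphs)
  model <- gnn_init(model_config, seed = config$seed)
  pnames <- names(model$params)
  mstate <- lapply(model$params, function(m) m * 0)
  vstate <- lapply(model$params, function(m) m * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  es <- list(counter = 0L)
  best_params <- model$params
  best_epoch <- 0L
  hist <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    tape <- ad_tape()
    pn <- .params_to_nodes(tape, model$params, trainable = TRUE)
    thetas <- numeric(n)
    outs <- vector("list", n)
    for (s in seq_len(n)) {
      outs[[s]] <- .gnn_forward_tape(tape, pn, graphs[[s]], model$config)
      thetas[s] <- ad_value(outs[[s]]$theta)[1, 1]
    }
    lc <- vapply(outs, function(o) ad_value(o$l_cut)[1, 1], numeric(1))
    lo <- vapply(outs, function(o) ad_value(o$l_ortho)[1, 1], numeric(1))
    cox <- cox_partial_loss(thetas, tm, ev)
    loss <- total_loss(cox, mean(lc), mean(lo), config$lambda)
    if (!is.finite(loss))
      stop("numerical error: non-finite loss at epoch ", epoch)
    gth <- .cox_loss_grad(thetas, tm, ev)
    outputs <- list(); seeds <- list()
    for (s in seq_len(n)) {
      outputs <- c(outputs, list(outs[[s]]$theta, outs[[s]]$l_cut,
                                 outs[[s]]$l_ortho))
      seeds <- c(seeds, list(matrix(gth[s], 1, 1),
                             matrix(config$lambda / n, 1, 1),
                             matrix(config$lambda / n, 1, 1)))
    }
    ad_backward(outputs, seeds)
    for (k in seq_along(pnames)) {
      nm <- pnames[k]
      g <- ad_grad(pn[[nm]])
      if (is.null(g)) g <- model$params[[nm]] * 0
      g <- g + config$weight_decay * model$params[[nm]]
      mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
      vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
      mh <- mstate[[nm]] / (1 - b1^epoch)
      vh <- vstate[[nm]] / (1 - b2^epoch)
      model$params[[nm]] <- model$params[[nm]] - config$lr * mh / (sqrt(vh) + eps)
    }
    hist[[epoch]] <- data.frame(epoch = epoch, cox = cox,
                                l_cut = mean(lc), l_ortho = mean(lo),
                                total = loss)
    if (config$verbose)
      message(sprintf("epoch %3d  cox %.4f  cut %.4f  ortho %.4f",
                      epoch, cox, mean(lc), mean(lo)))
    es <- .early_stop_update(es, loss, config$min_delta, config$patience)
    if (es$improved) {
      best_params <- model$params
      best_epoch <- epoch
    }
    if (es$stop) break
  }
  model$params <- best_params
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$best_epoch <- best_epoch
  model$sample_ids <- ids
  model$train_config <- config
  model
}

#' Risk scores for a list of sample graphs
#'
#' @param model a trained (or initialized) `gnn_model`
#' @param graphs list of [build_sample_graph()] objects
#' @return Named numeric vector of risk scores, in input order.
#' @export
predict_risk <- function(model, graphs) {
  out <- vapply(graphs, function(g) gnn_forward(model, g)$theta, numeric(1))
  names(out) <- vapply(graphs, function(g) g$sample_id, character(1))
  out
}

#' Maximally selected rank-statistic cutpoint
#'
#' Evaluates every candidate cut between consecutive distinct risk
#' scores that leaves at least `minprop` of the cohort on each side,
#' and picks the one maximizing the absolute standardized two-group
#' log-rank statistic; ties go to the lower cutoff. No multiplicity
#' adjustment is applied to the reported p-value -- downstream
#' validation cohorts carry the inferential claim.
#'
#' @param scores numeric risk scores
#' @param surv a [survival_table()] aligned with `scores`
#' @param minprop minimum proportion per group (default 0.1)
#' @return A list of class `cutpoint_result`: `cutoff`, `statistic`
#'   (absolute standardized log-rank at the cut), `z` (signed), `p`
#'   (unadjusted), `groups` (factor high/low per sample; high means
#'   score > cutoff).
#' @export
optimal_cutpoint <- function(scores, surv, minprop = 0.1) {
  n <- length(scores)
  if (n != nrow(surv))
    stop("input error: scores and survival table lengths differ")
  if (sum(surv$event) < 1) stop("input error: at least one event required")
  us <- sort(unique(scores))
  if (length(us) < 2)
    stop("cutpoint error: all risk scores identical")
  cuts <- (us[-length(us)] + us[-1]) / 2
  minn <- max(1, ceiling(minprop * n))
  best <- NULL
  for (ct in cuts) {
    hi <- scores > ct
    if (sum(hi) < minn || sum(!hi) < minn) next
    lr <- tryCatch(logrank_test(surv, hi), error = function(e) NULL)
    if (is.null(lr)) next
    sc <- abs(lr$z)
    if (is.null(best) || sc > best$statistic + 1e-12) {
      best <- list(cutoff = ct, statistic = sc, z = lr$z, p = lr$p)
    }
  }
  if (is.null(best))
    stop("cutpoint error: no admissible cut under minprop = ", minprop)
  groups <- factor(ifelse(scores > best$cutoff, "high", "low"),
                   levels = c("low", "high"))
  structure(c(best, list(groups = groups, minprop = minprop)),
            class = "cutpoint_result")
}
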