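# Simulator for paired single-cell / bulk cohorts with planted,
# recoverable prognostic structure. Bulk expression follows correlated
# log-scale gene modules driven by per-sample latent factors; a subset
# of planted genes carries log-hazard effects on exponential event
# times with uniform censoring tuned to a target rate. Single cells
# share the module structure through per-cell module activities (with
# cell-type shifts), so cell-to-sample rank correlations carry signal
# for the planted genes.

#' Simulation configuration
#'
#' Defaults describe a desk-scale cohort: 120 samples, 300 genes in 6
#' correlated modules, 500 cells from 4 cell types, 20 planted
#' prognostic genes with unit log-hazard effects, 30% censoring and
#' 60% dropout.
#'
#' @param n_samples,n_genes,n_cells,n_celltypes cohort dimensions
#' @param n_prognostic number of planted prognostic genes
#' @param beta planted log-hazard effects (recycled/truncated to
#'   `n_prognostic`); by default every planted gene in the same risk
#'   module shares the sign (+1 for odd modules, -1 for even), so
#'   correlated effects reinforce rather than cancel
#' @param base_hazard baseline exponential hazard per month
#' @param censor_rate_target desired fraction of censored samples
#' @param dropout single-cell zero-inflation probability
#' @param noise_sd log-scale Gaussian noise sd
#' @param n_modules number of correlated gene modules; the first
#'   `n_risk_modules` are reserved for the planted prognostic genes,
#'   the rest hold null genes
#' @param n_risk_modules modules carrying the planted genes
#' @param seed RNG seed; all outputs are deterministic given it
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 120, n_genes = 300, n_cells = 500,
                       n_celltypes = 4, n_prognostic = 20,
                       beta = NULL, base_hazard = 0.02,
                       censor_rate_target = 0.3, dropout = 0.6,
                       noise_sd = 0.4, n_modules = 6, n_risk_modules = 2,
                       seed = 1) {
  if (n_prognostic > n_genes)
    stop("config error: n_prognostic exceeds n_genes")
  if (n_celltypes > n_cells)
    stop("config error: more cell types than cells")
  if (base_hazard <= 0)
    stop("config error: base_hazard must be positive")
  if (n_risk_modules >= n_modules)
    stop("config error: need at least one null module")
  if (censor_rate_target < 0 || censor_rate_target >= 1 ||
      dropout < 0 || dropout > 1)
    stop("config error: rates must be probabilities")
  risk_module <- rep(seq_len(n_risk_modules), length.out = n_prognostic)
  if (is.null(beta)) beta <- ifelse(risk_module %% 2 == 1, 1, -1)
  beta <- rep(beta, length.out = n_prognostic)
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_cells = n_cells, n_celltypes = n_celltypes,
                 n_prognostic = n_prognostic, beta = beta,
                 base_hazard = base_hazard,
                 censor_rate_target = censor_rate_target,
                 dropout = dropout, noise_sd = noise_sd,
                 n_modules = n_modules, n_risk_modules = n_risk_modules,
                 seed = seed),
            class = "sim_config")
}

# shared latent structure: the planted genes occupy dedicated risk
# modules (strong unit loadings) so their expression tracks the latent
# hazard factors; all remaining genes sit in null modules.
.sim_structure <- function(cfg) {
  set.seed(cfg$seed)
  planted <- seq_len(cfg$n_prognostic)
  module <- integer(cfg$n_genes)
  module[planted] <- rep(seq_len(cfg$n_risk_modules),
                         length.out = cfg$n_prognostic)
  null_mods <- seq(cfg$n_risk_modules + 1, cfg$n_modules)
  module[-planted] <- rep(null_mods, length.out = cfg$n_genes - cfg$n_prognostic)
  loading <- stats::runif(cfg$n_genes, 0.3, 0.8)
  loading[planted] <- 1
  mu <- stats::runif(cfg$n_genes, 1, 4)
  list(module = module, loading = loading, mu = mu, planted = planted)
}

#' Simulate a bulk cohort with censored survival
#'
#' @param cfg a [sim_config()]
#' @return A list of class `sim_bulk`: `bulk` (an
#'   [expression_matrix()]), `surv` (a [survival_table()]), `truth`
#'   (planted gene ids, betas, per-sample linear predictor, realized
#'   censoring fraction).
#' @export
simulate_bulk_and_survival <- function(cfg) {
  st <- .sim_structure(cfg)
  set.seed(cfg$seed + 1)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  samples <- sprintf("s%03d", seq_len(cfg$n_samples))
  Fms <- matrix(stats::rnorm(cfg$n_modules * cfg$n_samples),
                cfg$n_modules, cfg$n_samples)
  # risk-program activity is bimodal across patients (distinctly up-
  # or down-regulated), so each sample expresses every risk program
  # with a clear sign; null-module factors stay Gaussian
  nr <- cfg$n_risk_modules
  sgn <- matrix(sign(stats::runif(nr * cfg$n_samples) - 0.5),
                nr, cfg$n_samples)
  mag <- 0.6 + abs(matrix(stats::rnorm(nr * cfg$n_samples, sd = 0.8),
                          nr, cfg$n_samples))
  Fms[seq_len(nr), ] <- sgn * mag
  X <- st$mu + st$loading * Fms[st$module, , drop = FALSE] +
    cfg$noise_sd * matrix(stats::rnorm(cfg$n_genes * cfg$n_samples),
                          cfg$n_genes, cfg$n_samples)
  dimnames(X) <- list(genes, samples)
  Z <- t(scale(t(X[st$planted, , drop = FALSE])))
  eta <- drop(cfg$beta %*% Z)
  Tev <- stats::rexp(cfg$n_samples, rate = cfg$base_hazard * exp(eta))
  Tev <- pmax(Tev, 1e-3)
  if (cfg$censor_rate_target > 0) {
    # uniform censoring C ~ U(0, cmax); P(censored | T) = min(T/cmax, 1)
    f <- function(cmax) mean(pmin(Tev / cmax, 1)) - cfg$censor_rate_target
    cmax <- stats::uniroot(f, lower = min(Tev) * 1e-3,
                           upper = max(Tev) * 1e3)$root
    Cc <- stats::runif(cfg$n_samples, 0, cmax)
  } else {
    Cc <- rep(Inf, cfg$n_samples)
  }
  time <- pmin(Tev, Cc)
  event <- as.integer(Tev <= Cc)
  if (sum(event) == 0)
    stop("config error: simulated cohort has no events")
  structure(list(
    bulk = expression_matrix(X, genes, samples, "bulk"),
    surv = survival_table(samples, time, event),
    truth = list(planted_genes = genes[st$planted], beta = cfg$beta,
                 eta = stats::setNames(eta, samples),
                 censor_fraction = mean(event == 0),
                 seed = cfg$seed)),
    class = "sim_bulk")
}

#' Simulate single cells sharing the bulk module structure
#'
#' Cells are drawn from cell-type centroids with Gaussian log-scale
#' noise; at `noise_sd = 0` and `dropout = 0` every cell equals its
#' centroid exactly. Centroid loadings reuse the bulk module
#' structure -- cell types express the risk modules at distinct
#' levels -- so cell-to-sample Spearman correlations carry signal for
#' the planted genes. Zero-inflation is applied at rate `dropout`.
#'
#' @param cfg a [sim_config()]
#' @return A single-cell [expression_matrix()] over the same genes.
#' @export
simulate_cells <- function(cfg) {
  st <- .sim_structure(cfg)
  set.seed(cfg$seed + 2)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  cells <- sprintf("c%04d", seq_len(cfg$n_cells))
  ctype <- rep(seq_len(cfg$n_celltypes), length.out = cfg$n_cells)
  # module activity per cell type: risk programs differ sharply across
  # cell types, null modules only mildly
  act_sd <- c(rep(1.5, cfg$n_risk_modules),
              rep(0.4, cfg$n_modules - cfg$n_risk_modules))
  shift <- act_sd * matrix(stats::rnorm(cfg$n_modules * cfg$n_celltypes),
                           cfg$n_modules, cfg$n_celltypes)
  centroids <- st$mu + st$loading * shift[st$module, , drop = FALSE]
  centroids <- pmax(centroids, 0)
  Y <- centroids[, ctype, drop = FALSE]
  if (cfg$noise_sd > 0)
    Y <- Y + cfg$noise_sd * matrix(stats::rnorm(cfg$n_genes * cfg$n_cells),
                                   cfg$n_genes, cfg$n_cells)
  Y <- pmax(Y, 0)
  if (cfg$dropout > 0) {
    drop <- matrix(stats::runif(cfg$n_genes * cfg$n_cells) < cfg$dropout,
                   cfg$n_genes, cfg$n_cells)
    Y[drop] <- 0
  }
  dimnames(Y) <- list(genes, cells)
  expression_matrix(Y, genes, cells, "single_cell")
}

#' Generate and optionally write a full simulated dataset
#'
#' Composes [simulate_bulk_and_survival()] and [simulate_cells()] and,
#' when `dir` is given, writes the files in the formats [read_expression()]
#' and [read_survival()] consume, plus a `truth.json` record of the
#' planted structure.
#'
#' @param cfg a [sim_config()]
#' @param dir output directory (created if missing); `NULL` to skip
#'   writing
#' @param sc_format `"csv"` or `"mtx"` for the single-cell matrix
#' @return A list of class `sim_dataset`: `bulk`, `sc`, `surv`,
#'   `truth`, `paths` (when written).
#' @export
generate_dataset <- function(cfg = sim_config(), dir = NULL,
                             sc_format = c("csv", "mtx")) {
  sc_format <- match.arg(sc_format)
  bs <- simulate_bulk_and_survival(cfg)
  sc <- simulate_cells(cfg)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop("I/O error: cannot create directory ", dir)
    paths <- list(
      bulk = file.path(dir, "bulk.csv"),
      sc = file.path(dir, if (sc_format == "csv") "sc.csv" else "sc.mtx"),
      survival = file.path(dir, "survival.csv"),
      truth = file.path(dir, "truth.json"))
    write_expression(bs$bulk, paths$bulk, "csv")
    write_expression(sc, paths$sc, sc_format)
    write_survival(bs$surv, paths$survival)
    jsonlite::write_json(
      list(planted_genes = bs$truth$planted_genes,
           beta = bs$truth$beta, seed = cfg$seed,
           censor_fraction = bs$truth$censor_fraction,
           config = unclass(cfg)),
      paths$truth, auto_unbox = TRUE, digits = NA)
  }
  structure(list(bulk = bs$bulk, sc = sc, surv = bs$surv,
                 truth = bs$truth, paths = paths, config = cfg),
            class = "sim_dataset")
}
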