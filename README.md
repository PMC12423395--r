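# scgraphsurv

Survival modelling on sample-specific gene graphs built from paired
single-cell and bulk transcriptomes.

Single-cell RNA-seq resolves the cellular heterogeneity of a tumour
but almost never comes with outcome data; bulk cohorts have survival
follow-up but average over cell populations. `scgraphsurv` connects
the two for analysts who want patient-level risk models that remain
interpretable at the gene-interaction level: it screens
survival-associated genes on the bulk cohort, scores every cell
against every bulk sample by rank correlation to pick **key genes per
patient**, wires those genes into per-patient graphs, and trains an
attention-based graph network to produce a risk score per patient,
together with node/edge/module statistics that explain which gene
interactions drive the stratification.

## The model

Each patient $s$ is a graph $G_s = (V_s, A_s)$ whose nodes are that
patient's key genes (selected by the signed significance score
$\mathrm{score} = \operatorname{sign}(\rho)(1 - 2\,\mathrm{FDR})$ with
$|\mathrm{score}| > 0.995$, $\mathrm{FDR} < 0.05$), and whose edges are
the induced subgraph of a fused k-nearest-neighbour gene graph (an
edge survives if present in either the single-cell or the bulk
modality). A graph attention network computes, per layer and head,

$$e_{ij} = \mathrm{LeakyReLU}\!\big(a^\top [W h_i \,\Vert\, W h_j]\big),
\qquad
\alpha_{ij} = \frac{\exp e_{ij}}{\sum_{k \in \mathcal N_i} \exp e_{ik}},
\qquad
h_i' = \mathrm{ELU}\Big(\sum_{j \in \mathcal N_i} \alpha_{ij} W h_j\Big),$$

followed by MinCut pooling into $K$ clusters (with the relaxed
normalized-cut and orthogonality regularizers) and a two-layer
Transformer encoder over the pooled tokens plus a class token whose
read-out is the risk score $\theta_s$. Training minimizes

$$\mathcal L \;=\; -\sum_{i \in E}\Big(\theta_i - \log\!\!\sum_{j:\,T_j \ge T_i}\!\! e^{\theta_j}\Big)
\;+\; \lambda\,\big(\ell_{\mathrm{cut}} + \ell_{\mathrm{ortho}}\big),$$

the Cox partial likelihood over the uncensored set $E$ plus the
pooling penalties, full-cohort with Adam and early stopping. Scores
are dichotomized at the maximally selected log-rank cutpoint, and the
trained attention coefficients are aggregated into per-cohort node
importances, edge weights, driver edges (risk specificity > 0.5,
frequency > 20%, key-gene endpoints) and Louvain modules.

All of this — including the reverse-mode autodiff the network trains
with — is implemented in R; see `vignette("methods")` for assumptions,
parameter meanings, and design decisions.

## Worked example

A complete run on a simulated cohort (120 patients, 300 genes, 500
cells, 20 planted prognostic genes; 80 patients train the model, 40
are held out):

```r
library(scgraphsurv)

cfg <- sim_config(seed = 1)            # study-condition defaults
ds  <- generate_dataset(cfg)

set.seed(1)
train <- sort(sample(ds$surv$sample_id, 80))
test  <- setdiff(ds$surv$sample_id, train)

st <- run_pipeline(ds$sc, ds$bulk, ds$surv,
                   min_genes = 15,
                   train_cfg = train_config(lr = 5e-3, max_epochs = 40,
                                            patience = 8, seed = 1),
                   train_ids = train, minprop = 0.2, seed = 1)

sv_test <- ds$surv[match(test, ds$surv$sample_id), ]
concordance_index(st$risk_scores[test], sv_test)$cindex
logrank_test(sv_test, st$risk_groups[test] == "high")$p
st$cutpoint$cutoff
head(st$node_stats[order(-st$node_stats$importance_global),
                   c("gene_id", "importance_global", "risk_bias", "is_key")])
```

which prints (elapsed about a minute on one CPU):

```
key-gene fallback (top-15 by |score|) for 113 sample(s)
[1] 0.9528158
[1] 2.2905e-11
[1] -0.93323
   gene_id importance_global   risk_bias is_key
6    g0006         0.7994920 -0.23376118   TRUE
21   g0208         0.7634889  0.04996911  FALSE
20   g0020         0.7622114 -0.12915008   TRUE
17   g0017         0.7539742 -0.21338727  FALSE
14   g0014         0.7495781 -0.28624958   TRUE
13   g0013         0.7489963  0.23690856   TRUE
```

The held-out C-index says how often, among comparable held-out pairs,
the patient with the higher predicted risk fails first (0.5 = chance);
the log-rank p-value tests the survival split between the high- and
low-risk groups defined by the training-cohort cutoff; the node table
ranks genes by mean attention mass, with `risk_bias` > 0 marking genes
whose attention concentrates in high-risk patients.

## Command line

A thin CLI wraps the same functions:

```sh
inst/cli/scgraphsurv simulate --out data/ --seed 1
inst/cli/scgraphsurv run --sc data/sc.csv --bulk data/bulk.csv \
    --surv data/survival.csv --out results/
```
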