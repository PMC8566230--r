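# nbgf — growth-factor signaling analysis of neuroblastoma transcriptomes

Neuroblastoma tumors carry few recurrent mutations, but their expression of
growth-factor receptors and downstream kinases varies enormously and tracks
both outcome and therapy escape. `nbgf` is an R package for analyzing that
axis of variation in bulk transcriptome cohorts. It provides, end to end:

* **Tumor subtyping** — UMAP embedding (correlation metric) of
  fold-from-mean expression plus HDBSCAN density clustering (implemented
  in-package), with cluster-vs-rest Mann–Whitney DEG calling and a
  cell-line cluster score `S = Σ log2(exp_i)·c_i`.
* **A MYCN-stratified survival model** — two-round elastic-net logistic
  regression `p(z) = 1/(1+e^{-z})`, `z = y0 + Σ ω_i·exp_i`, trained
  separately for MYCN-amplified and non-amplified tumors, with risk-group
  binning of predicted survival (`<40%` … `>95%`).
* **Pathway activation levels (PAL)** — role-weighted mean of log2
  case-to-normal ratios, `PAL = Σ ARR·log2(CNR) / Σ|ARR|`, with unpaired
  t-tests and FDR over pathways for phenotype contrasts (therapy response,
  metastasis).
* **Pre-ranked GSEA** — weighted running-sum enrichment score, gene-set
  permutation null, NES / nominal p / sign-stratified FDR, top-set
  selection.
* **GPScore** — the gene-set prognostic score `Nu/(Nu+Nf)`: per-gene
  Kaplan–Meier median-split prognosis with Bonferroni correction, set
  scoring, a 20-random-set null with a 3σ band, cross-dataset t-test
  significance, shared-set counting, and per-sample mean-squared-expression
  set scores with quartile stratification.
* **Dose–response tools** — viability normalization, robust (soft-L1)
  four-parameter-logistic IC50 fitting, Bliss-independence synergy scoring,
  and growth-factor protection statistics (Friedman test across cell
  lines).
* **A synthetic-cohort generator** — log-normal expression with planted
  clusters, MYCN strata, Weibull proportional-hazards survival tied to
  planted prognostic genes, co-expression modules, planted pathway shifts,
  and Bliss-consistent dose grids; every downstream stage is testable
  against recorded ground truth without any external download.

See `vignettes/growth-factor-signaling.Rmd` for the models, assumptions,
and design decisions.

## Worked example

```r
library(nbgf)

## simulate a 600-tumor cohort with 3 expression subtypes and 10 prognostic genes
beta <- setNames(c(rep(2, 5), rep(-2, 5)), sprintf("G%04d", 101:110))
cfg  <- synth_config(n_samples = 600, n_genes = 150, prognostic_genes = beta, seed = 7)
coh  <- generate_cohort(cfg)
expr <- normalize_fold_from_mean(coh$expr)

## subtype: UMAP embedding + HDBSCAN density clustering
cl <- embed_and_cluster(expr, min_cluster_size = 50, min_samples = 25, seed = 7)
cl
#> cluster_model: 600 samples, 3 cluster(s), 0 noise
adjusted_rand_index(cl$labels, coh$truth$cluster)
#> [1] 1

## cluster DEGs and the MYCN-stratified two-round survival model
degs <- call_cluster_degs(expr, cl$labels)
sum(degs$q < 0.05)
#> [1] 187
model <- train_two_round(expr, coh$clinical, gene_ids(expr), seed = 7)
model
#> survival_model: 23-gene merged panel (amp 15, non-amp 15), landmark 1825 d
length(intersect(names(beta), model$panel))
#> [1] 10

p <- predict_survival(model, expr, coh$clinical$mycn)
table(stratify_risk(p))
#>   <40% 40-60% 60-80% 85-95%   >95%
#>    275     57    113     70     85
```

The clustering recovers the three planted subtypes exactly (adjusted Rand
index 1), the two-round model's merged gene panel contains all ten planted
prognostic genes, and the predicted survival probabilities spread the
cohort across the five risk groups — the planted hazard effects are strong,
so many tumors land in the extreme bins.

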