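# screg

Single-cell cis-regulatory relationship inference with causal graph
attention.

## What it does, and for whom

A cis-regulatory relationship (CRR) is a directed link from a cis-regulatory
element (CRE; an accessible region observed as an scATAC-seq peak) to the
gene it regulates. `screg` is for genomics groups with paired scATAC-seq and
scRNA-seq data who want cell-type-resolved CRE→gene links — for example to
assign effector genes and effector cell types to non-coding GWAS variants.

The method:

1. restricts candidate CRE→gene edges to an **empirical evidence graph**
   built from promoter windows (TSS ± 2 kb), chromatin contacts (Hi-C/pcHi-C
   BEDPE) and eQTL associations;
2. optionally pretrains a **masked graph autoencoder** (two GAT encoder
   layers, one decoder layer) on per-cell CRE–CRE accessibility graphs with
   a scaled cosine error `mean((1 − cos(x_m, z_m))^γ)`, γ = 2;
3. trains a **causal graph-attention model**: one GAT layer whose effective
   adjacency is the evidence adjacency times a causal mask (attention flows
   only CRE→gene and over self-loops), pooled into a per-gene output
   `u(gene)`, standardized, softmaxed, and fit by
   `KL(u(pred) ‖ u(true)) + λ · weighted cross-entropy` against each cell
   type's normalized pseudobulk expression and the cell-type label (λ = 1);
4. computes per-cell **regulation scores** for every evidence edge by
   integrated gradients over edge weights (baseline 0, input 1), scaled as
   `RS = tanh(IG / SD(IG))` into (−1, 1).

Benchmark utilities score predictions against validated cell-type-specific
links (cell-level/reg-level AUC, AUPR ratio vs the prevalence baseline,
distance-stratified from 0–10 kb up to 0.3–1 Mb), and downstream helpers map
GWAS SNPs (p < 1e-5) to CREs, Z-scale per-type scores across cell types,
call marker CRRs/genes, and scan enhancer sequence with JASPAR PWMs
(relative score ≥ 0.8, exact-enumeration p < 0.05).

Everything — networks, Adam, and a small reverse-mode autodiff engine — is
implemented in base R with `Matrix` and Bioconductor interval machinery, so
the package runs on a single CPU with no deep-learning framework.

## Worked example

The synthetic generator plants ground-truth CRRs so the whole pipeline runs
without downloads:

```r
library(screg)

spec <- fixture_spec(n_cells_per_type = 12, n_cres = 60, n_genes = 10,
                     n_true_crrs = 15, n_decoy_edges = 20, seed = 7)
fx <- generate_fixture(spec)

res <- run_pipeline(fx, tempfile("example"), config = list(
  seed = 3, mode = "wop",               # no pretraining, fastest mode
  train = list(epochs = 8),
  markers = list(n_per_type = 10),
  attribution = list(steps = 16)))

print(res$model)
print(res$scores)
print(res$evaluation$report)
head(sort(colMeans(res$scores$scores), decreasing = TRUE), 3)
```

```
gcat_model (wop): 10 genes, 3 cell types, hidden_dim=64 [trained, best epoch 2]
regulation_scores: 14 cells x 30 CRR edges (3 cell types)
metric_report: mean cell-level AUC 0.935 (AUPR ratio 4.95), mean reg-level AUC 1.000 (AUPR ratio 3.00)
  3 cell types, 11 validated links
creP009::gene09 creP001::gene01 creP005::gene05
      0.9969440       0.9904469       0.9835446
```

Reading the output: the trained model kept the epoch with the best
validation KL; the score matrix has one row per held-out test cell and one
column per evidence edge (`creId::geneId`); a mean cell-level AUC of 0.935
means each cell type's scores rank its planted links above decoys far better
than chance (0.5), and an AUPR ratio of 4.95 means ~5× the precision-recall
area of a random predictor at this class balance. The top-scoring columns
are planted CREs (ids `creP*`) paired with their true target genes.

The same stages are available piecewise (`filter_cells_by_peak_count`,
`lsi_embed`, `aggregate_neighbors`, `build_cre_gene_graph`, `pretrain_ssgae`,
`train_simulation`, `attribute_test_set`, `match_predictions_to_truth`, …);
a thin command-line wrapper lives at `inst/cli/screg.R` with `simulate`,
`run-all`, `evaluate` and `variants` subcommands.

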