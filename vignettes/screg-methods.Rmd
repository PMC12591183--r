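---
title: "Inferring single-cell cis-regulatory relationships with causal graph attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring single-cell cis-regulatory relationships with causal graph attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A cis-regulatory relationship (CRR) is a directed functional link from a
cis-regulatory element (CRE — an accessible region such as an enhancer or
promoter, observed as an scATAC-seq peak) to a target gene. Knowing which
CREs regulate which genes, and in which cell types, is central to
interpreting non-coding disease variants: most GWAS hits fall in regulatory
DNA, and their effector genes and effector cell types are usually unknown.

`screg` infers CRRs with per-cell **regulation scores** from paired
single-cell chromatin accessibility (scATAC-seq) and expression (scRNA-seq)
data. Its two organizing ideas are:

1. **Evidence-constrained candidate links.** Rather than considering every
   peak within a distance window of every gene, candidate CRE→gene edges are
   restricted to an empirical evidence graph assembled from promoter
   windows, chromatin contacts (Hi-C/pcHi-C) and eQTL associations. This
   removes most spurious distance-based candidates while retaining long-range
   links that contact and eQTL data support.
2. **Causal direction built into the architecture.** A graph-attention layer
   runs under a *causal attention mask* that admits information flow only
   along evidence CRE→gene edges (plus self-loops). Gene→CRE and CRE→CRE
   attention is structurally zero, so the trained model — and any gradient
   taken through it — cannot attribute a gene's predicted expression to a
   CRE that no evidence links to it.

## Model

### Evidence graphs

Two graphs share the same construction rules ("overlap" always means ≥ 1 bp
intersection of 0-based half-open intervals; promoter = TSS ± 2 kb):

* **CRE–CRE graph** (undirected; used for autoencoder pretraining): two CREs
  are connected if they overlap the same promoter window; all CREs in one
  contact fragment are connected to all CREs in the other; and for each eQTL,
  the promoter CREs of its gene are connected to the CRE overlapping the SNP.
* **CRE→gene graph** (directed; the candidate CRRs): a CRE links to a gene
  if it overlaps the gene's promoter window; CREs in one contact fragment
  link to genes whose promoter window overlaps the other fragment (applied
  in both fragment orders, since a contact is unordered — `hic_symmetric`
  disables this); and an eQTL links the SNP-overlapping CRE to its gene.
  Duplicate edges are merged with provenances unioned.

The causal mask is `mask[i, j] = 1` iff `i → j` is an evidence CRE→gene edge
or `i = j`. Self-loops are included so that attention over a node's
neighborhood is always defined; a gene's self-loop also carries its own
initialized feature into its output.

### Preprocessing

Accessibility: cells outside the 1st–99th percentile of captured-peak counts
are removed (linear-interpolation percentiles, strict thresholds); peaks
must be detected in at least 5% of the cells of *every* type (inclusive
boundary); the matrix is embedded by LSI (library-size normalization, top
50 000 variable features, per-feature scaling, TF-IDF with
`idf = log(1 + n/df)`, truncated SVD to 50 components) and each cell's raw
counts are summed with its 10 Euclidean nearest neighbors (11 cells total)
to mitigate sparsity. Expression: per-type pseudobulk profiles over a
marker-gene union (a cosine-based score against each type's indicator
vector, 300 genes per type by default), each type's profile normalized to
sum to 1. These profiles are the training targets; only marker genes enter
the model.

### Masked graph autoencoder (SSGAE)

Per cell, the CRE–CRE graph with that cell's accessibility as node features
is a training example. Raw features are scalars, on which a cosine
reconstruction error is degenerate, so features are first lifted to the
64-dimensional hidden space by a learnable linear embedding; 50% of nodes
are then replaced by a learnable mask token. A two-layer GAT encoder (4
heads of 16, concatenated; LeakyReLU between layers) embeds the corrupted
graph and a one-layer GAT decoder (4 heads averaged) reconstructs it. The
loss is the scaled cosine error over masked nodes,

$$\mathcal{L} = \frac{1}{|\tilde V|}\sum_{m \in \tilde V}
  \left(1 - \cos(x_m, z_m)\right)^{\gamma}, \qquad \gamma = 2,$$

with the reconstruction target being the lifted encoder-input features under
a stop-gradient (reconstructing a quantity the loss itself could otherwise
collapse). γ > 1 down-weights already-well-reconstructed nodes. Training is
Adam (learning rate 1e-4, weight decay 1e-4), one graph per step, attention
dropout 0.5.

### Cis-regulation simulation (GCAT)

For each cell, node features over the CRE→gene graph are the cell's
aggregated accessibility (as `log1p` counts); each gene node is initialized
with the accessibility of the CRE whose midpoint is nearest its TSS (ties to
the smaller start coordinate). Two encodings are concatenated: a fresh
linear+ReLU encoding, and the frozen SSGAE encoder's embedding of the same
features (omitted entirely in the no-pretraining mode). One GAT layer runs
under the causal mask; its output is pooled per node by the mean over the
hidden dimension, gene entries are extracted as $u^{(gene)}$, standardized
($\varepsilon = 10^{-5}$ in the denominator) and softmaxed into a predicted
expression distribution. The loss combines

* the KL divergence between the predicted distribution and the cell type's
  normalized pseudobulk profile, and
* a class-balanced cross-entropy (weights $1/N_c$ from training-set counts)
  on a 2-layer perceptron cell-type classifier over the standardized gene
  vector, weighted by λ = 1.

Training uses Adam (learning rate 5e-4, weight decay 1e-4) on a stratified
50/10/40 train/validation/test split of cells; the checkpoint with the best
validation KL is kept, with early stopping after 10 stalled epochs. The
pseudobulk targets are computed from train+validation cells only, so test
cells never inform the prior.

### Regulation scores by integrated gradients

Edge weights multiply the normalized attention coefficients, so scaling all
evidence-edge weights from a 0 baseline to their actual value 1 and
integrating the gradient of a gene's predicted expression along that path
(midpoint Riemann sum, 64 steps by default) attributes the prediction to
individual edges. Because the mask routes each evidence edge into exactly
its target gene, the gradient of the *sum* of gene outputs yields every
edge's attribution with respect to its own gene in one backward pass. Per
cell, attributions are divided by their population standard deviation and
squashed with `tanh`, giving regulation scores in (−1, 1). Attribution of
the default target (the pre-softmax pooled gene output) is exact at any step
count because that output is linear in the edge weights; a `prob` target
(the softmax probability) is available and is genuinely path-dependent.

### Ablation modes

* `full` — SSGAE pretrained on a multi-tissue atlas corpus;
* `posd` — SSGAE pretrained only on the study's own accessibility data;
* `wop` — no pretrained embeddings; the GCAT input is the fresh encoding
  alone.

The pipeline manifest records the mode and pretraining corpus, so runs are
distinguishable after the fact.

## Evaluation

Predictions are compared against validated cell-type-specific links
(chromatin contacts or CRISPRi). A score-matrix edge is a positive for type
*t* if a validated entry overlaps its CRE by ≥ 1 bp, names the same gene and
carries type *t*; only edges with CRE–TSS distance ≤ 1 Mb are evaluated.
Four metrics: **cell-level AUC** (can a type's mean scores separate its
validated links from the rest), **reg-level AUC** (can one validated link's
scores across types single out the correct type), and their AUPR ratios
(AUPR divided by the random-predictor baseline, i.e. the positive
prevalence; > 1 beats random). Distance stratification uses five bins, 0–10
kb, 10–50 kb, 50–100 kb, 100–300 kb and 300 kb–1 Mb; the outer boundaries
are standard in the enhancer-benchmark literature and the inner edges are
this package's convention.

## The synthetic study

`generate_fixture()` plants ground truth so the whole pipeline is testable
without downloads. On one synthetic chromosome, 40 genes and 300 CREs are
placed so planted CRE–TSS distances cover all five evaluation bins; 60
planted CRRs are each assigned an active cell type (3 types × 70 cells by
default). Accessibility counts are negative binomial — mean 5 for a CRE
active in the cell's type, 0.3 otherwise, dispersion 2 — values chosen to
mimic the sparsity of aggregated scATAC data. Expression is multinomial
(about 2 000 reads/cell) with gene probabilities softmax-proportional to
`0.4 ×` the summed accessibility of the cell's active incident CREs, so
expression is causally driven by accessibility through exactly the planted
edges; 0.4 per count puts a typical active gene roughly e² above background
without collapsing the distribution. Planted edges are emitted as promoter
placement, contact pairs or eQTL SNPs; 120 decoy edges use CREs at
background accessibility in every profiled type, emulating evidence imported
from tissues that were not profiled.

What the fixture does **not** emulate: accessible-but-inert enhancers (open
chromatin with no expression effect) as decoys, batch effects, doublets,
fragment-level noise, and realistic genome architecture. Passing the planted
recovery test therefore shows that the machinery learns and attributes the
accessibility→expression coupling it was given — not that the method
separates regulation from mere accessibility on real tissue.

### A known specificity limitation

With the expression coupling switched off (`effect_size = 0`) the planted
CREs remain type-specifically accessible while decoys stay closed. Because
attention coefficients are functions of node features only, integrated
gradients necessarily attribute open chromatin, and the cell-type classifier
head keeps type information in the gene vector even when expression carries
none. The pipeline therefore still ranks planted edges above closed decoys
(cell-level AUC ≈ 0.8 in the packaged null experiment) — the acceptance
suite states the chance-level expectation for this null and the
corresponding check documents the failure rather than hiding it. The
practical reading: a high regulation score requires accessible chromatin
plus evidence support, but is not by itself proof that accessibility drives
expression; claims of regulation should rest on the strong-signal contrast,
not the null.

## Numerical choices and degenerate inputs

* All networks run on a small reverse-mode autodiff tape written in base R;
  gradients are verified against central finite differences in the test
  suite. Determinism holds for fixed seeds under single-threaded BLAS.
* Glorot-uniform initialization; Adam with bias correction; L2 weight decay
  added to gradients.
* Softmax and log-sum-exp are computed with max-shifting; cosine norms carry
  an 1e-8 guard; KL floors the target at 1e-12; the classifier clamps a zero
  predicted probability at 1e-12 with a warning.
* Attention over an isolated node is undefined: callers always add
  self-loops, and `gat_forward()` rejects nodes without incoming edges.
* k-NN distance ties break by cell index; nearest-CRE ties by start
  coordinate; equal marker scores by gene id — all choices that make reruns
  bit-identical.
* A constant gene vector standardizes to zeros (the ε guard); a cell whose
  attributions have zero SD gets all-zero scores with a warning.
* The PWM scanner's p-values come from the exact null distribution of the
  log-odds score under i.i.d. uniform background, enumerated by dynamic
  programming on a 1e-3 score grid; queries are backed off by half a motif
  length in grid steps so discretization never excludes an attained score.
* LSI uses a dense SVD, appropriate for the package's desk scale (up to a
  few thousand cells); atlas-scale decompositions would need a truncated
  sparse solver.
* The marker-CRR test treats pairwise score distances as independent
  samples, which they are not; the Wilcoxon p-values run anticonservative
  and the Bonferroni correction absorbs only part of that. The test suite
  measures the realized null behavior instead of asserting the nominal rate.

## Problem sizes used by the packaged experiments

The default synthetic study is 210 cells × 300 CREs × 40 genes with 60
planted and about 180 candidate edges; simulation training runs at most 100
epochs with early stopping, and attribution uses 64 integrated-gradients
steps over the 84 test cells. Unit fixtures are 5–50 nodes so that every
oracle (dense attention, quadratic overlap, pair-counting AUC, exact PWM
enumeration) stays enumerable. These sizes were chosen so a complete run is
a coffee-break computation on one core while still spanning all five
distance bins and three evidence sources.

## Limitations

Beyond the specificity caveat above: the method requires matched (or at
least type-matched) accessibility and expression data with shared cell-type
labels; genes outside the marker union are not modeled; evidence quality
bounds attainable recall (a true CRR absent from promoter/contact/eQTL
evidence cannot be predicted); and the per-cell SD normalization makes
scores comparable within a cell but only loosely across datasets.
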