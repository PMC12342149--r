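---
title: "Estimating protein complex model accuracy with similarity graphs and a graph transformer"
author: "GraphEMA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating protein complex model accuracy with similarity graphs and a graph transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GraphEMA)
```

## The problem

Given a pool of predicted structural models (decoys) of one protein
complex and no experimental structure, estimate each decoy's global
accuracy — its true TM-score against the native — well enough to select
the best model. Two families of estimators exist: *single-model* methods
score a decoy from its own features and are robust to pool composition
but individually noisy; *consensus* methods score a decoy by its average
pairwise similarity to the rest of the pool (PSS) and are accurate when
good models are common, but fail predictably when a large cluster of
mutually similar mediocre models dominates: every member of that cluster
is "central", so consensus ranks one of them first (the central tendency
problem). GraphEMA integrates both signals in a graph model built to
survive that failure mode.

## Model

### Similarity graph

Decoys are nodes; an undirected edge joins decoys $i \neq j$ when their
pairwise TM-score is strictly greater than 0.5, the conventional
same-fold threshold. "Exceeds" is read strictly: a pair at exactly 0.5
is not connected. Pairwise input matrices may be asymmetric (structure
comparison tools normalize by either chain); they are symmetrized as
$(M + M^\top)/2$ because the graph is undirected and neither direction
is privileged — a warning flags pairs disagreeing by more than 0.05.
Isolated decoys stay in the graph; in attention their neighborhood
degenerates to the node itself, so they are still scored (from their
single-model features and consensus columns).

Node features (variant *basic*): mean pairwise TM-score and QS-score at
the full-graph and at the subgraph level (self excluded — the full-graph
TM column is numerically identical to the PSS baseline), and four
single-model scores, each multiplied by (decoy length / target length)
to penalize incomplete models, clipped back to $[0,1]$, and accompanied
by a 0/1 missingness mask. Missing scores are imputed with the pool
median of that score rather than zero, because upstream scorers fail on
scattered decoys in practice and silent zeros would bias the pool
statistics; the mask lets the network discount imputed values. Variant
*gcp* adds a fifth single-model score; *advanced* adds mean pairwise
interface metrics (DockQ averages, CAD-score) as node features and the
corresponding per-edge values as edge features. Edge features (all
variants): the number of common interaction interfaces — consumed as a
precomputed integer and scaled to $[0,1]$ by a configurable cap
(default 10, clipped), since no canonical definition of the count
exists — plus the pairwise TM-score and QS-score. All features lie in
$[0,1]$ by construction, so no further standardization is applied.

### Cluster-balanced subgraph sampling

The average pairwise similarity of the pool decides the sampling regime,
with the boundary value 0.8 assigned to the easy branch: pools with
average PSS $\ge 0.8$ are homogeneous and subgraphs of at most 50 nodes
are drawn uniformly; below 0.8, decoys are clustered and each subgraph
draws a near-equal number from every cluster. Clustering is K-means on
each decoy's row of the TM matrix (the similarity profile), with the
cluster number $k \in [2, 10]$ chosen by mean silhouette width
(Euclidean distance on the same rows) and ties broken toward smaller
$k$; K-means uses 10 seeded restarts. Only the TM matrix is clustered:
it is the metric that defines the graph, and the secondary metrics are
strongly correlated with it.

Per subgraph, each cluster contributes $\lfloor 50 / k \rfloor$ decoys
drawn without replacement; the remainder slots go one each to the
largest clusters, and clusters smaller than their quota contribute all
members with the shortfall redistributed to clusters that still have
spare members (exact equality is impossible for tiny clusters). Pools of
at most 50 decoys yield the full graph in every subgraph. Sampling is
independent across subgraphs, so a decoy can appear many times; after
the requested draws, a coverage-repair pass appends subgraphs around any
decoy never sampled, because aggregation needs at least one prediction
per decoy. The subgraph-level consensus columns are recomputed over the
subgraph's nodes — this is the mechanism that defeats the central
tendency: inside a balanced subgraph, the dominant cluster no longer
dominates the local consensus.

### Graph transformer

Raw node and edge features are embedded by two-layer MLPs (LeakyReLU,
slope 0.01). Each of $L$ layers then updates:

* **Attention.** Per head, logits are
  $q_i \cdot k_j / \sqrt{d_k} + b(e_{ij})$ for $j$ in the neighborhood
  of $i$, where $b(\cdot)$ is a learned per-head linear projection of
  the current edge embedding; the self term uses a learned scalar bias
  instead of an edge bias. The softmax runs over the closed neighborhood
  $N(i) \cup \{i\}$; non-neighbors receive exactly zero weight. Head
  outputs are concatenated and linearly projected. Attention is per-head
  (each head has its own weights over its own value slice).
* **Node update.**
  $h^{(l+1)}_i = \mathrm{LN}\!\big(h^{(l)}_i + \mathrm{MLP}(h^{(l)}_i +
  \mathrm{attn}_i)\big)$ — the MLP input carries the attention residual,
  an outer residual skips the whole block, and layer normalization is
  applied after the residual.
* **Edge update.**
  $e^{(l+1)}_{ij} = \mathrm{LN}\!\big(e^{(l)}_{ij} +
  \mathrm{MLP}(e^{(l)}_{ij} + P(h^{(l)}_i + h^{(l)}_j))\big)$ with a
  learned projection $P$ mapping node space to edge space. Each
  undirected edge stores one embedding used for both directions; the
  update input $h_i + h_j$ is symmetric, so edge embeddings remain
  direction-free exactly.

A two-layer MLP readout with a sigmoid bounds every node score to
$[0,1]$, matching the TM-score target. Dropout (default 0.1) acts on
MLP hidden activations in training mode only; evaluation is
deterministic. The forward pass is permutation-equivariant over nodes,
and the analytic backward pass is verified against finite differences
in the test suite (relative error below $10^{-4}$ on random
instances; in practice it agrees to $\sim 10^{-6}$).

### Loss and training

With labels $y_i$ (true TM-scores, used as-is) and predictions
$\hat y_i$,
$$L = \alpha \cdot \tfrac{1}{N}\textstyle\sum_i (y_i - \hat y_i)^2 +
      \beta \cdot \tfrac{1}{|P|}\textstyle\sum_{(i,j) \in P}
      (\Delta y_{ij} - \Delta\hat y_{ij})^2,$$
where $P$ is the set of all unordered decoy pairs *within a subgraph*
(at most $50 \cdot 49/2 = 1225$), the natural scope that keeps the loss
computable per batch. The pairwise term is invariant to constant shifts
and trains relative ranking directly. Defaults $\alpha = \beta = 1$;
both exposed. A single-node subgraph contributes zero pairwise loss with
a warning. Optimization is AdamW (default; plain SGD available) with
learning rate $10^{-3}$, weight decay $10^{-5}$, batches of 8 subgraphs;
gradients are computed by the package's own backward pass. After each
epoch the combined loss is evaluated on the validation subgraphs; the
checkpoint minimizing it is kept and training stops after a patience of
non-improving epochs. Cross-validation splits are by target, never by
decoy; the trainer audits that no validation target's subgraphs enter a
training batch. Checkpoints serialize to JSON (shape-tagged arrays, full
precision) with a version header, the configuration and the feature
names, so an incompatible checkpoint fails loudly instead of silently
mis-mapping features.

### Inference

Per decoy, predictions from all subgraphs containing it are aggregated
by mean (default — it matches the averaging used for ensembling) or
median (robust to outlier subgraphs), with the sample standard deviation
and the count reported. `repeatAndAverage()` reruns
sampling-plus-prediction with derived seeds and averages, reporting the
across-repeat dispersion that quantifies sampling randomness;
`ensemblePredictions()` takes the unweighted mean across checkpoints.
Aggregates always lie within the range of their inputs.

## Evaluation metrics

Per target: Pearson and Spearman correlation between predicted and true
scores; ranking loss $\max_i y_i - y_{\arg\max_i \hat y_i}$ (ties in
predictions broken toward the lexicographically smallest decoy id, for
reproducibility); and the Mann-Whitney AUC with positives defined as
true score at or above the 75% quantile (linear-interpolation empirical
quantile; the boundary is positive, since the metric's purpose is
recognizing the better quarter). Metrics are averaged over targets with
defined values; degenerate targets (zero variance, empty AUC class) are
excluded with a warning. Cross-predictor summaries standardize each
metric per target with the population standard deviation across
predictors (loss metrics flipped to $1 - \mathrm{loss}$ first) and sum
the z-scores over targets; missing predictor-target cells contribute
nothing, and an unweighted sum is used — the exact weights of official
assessor scores are not public, so weights are configurable but default
to 1.

## Synthetic benchmark

The generator plants cluster structure explicitly. Each cluster has a
size, a center quality, and a within-cluster spread; decoy $i$ in
cluster $c$ draws a 1-D latent deviation
$\varepsilon_i \sim N(0, \sigma_c)$ that drives both its label,
$y_i = \mathrm{clip}(q_c + \varepsilon_i)$, and its similarity to
cluster mates, $\mathrm{TM}(i,j) = \mathrm{clip}(1 - s\,
|\varepsilon_i - \varepsilon_j|)$ — so structural closeness and quality
closeness are coupled within a cluster, as they are for real decoys.
Between clusters the TM-score hovers around a configurable constant
(default 0.3) with small Gaussian jitter. The one-dimensional latent is
the simplest construction that yields block-structured matrices with
independently tunable within- and between-cluster similarity. QS-scores
mix the TM matrix with independent uniform noise (weight 0.8);
common-interface counts are $\mathrm{round}(5 \cdot \mathrm{TM})$;
single-model scores are $y_i$ plus Gaussian noise (SD 0.1), all clipped
to $[0,1]$. All randomness derives from one root seed through fixed
stream offsets, so every artifact is reproducible.

Presets define the study conditions: *central_tendency* (180 decoys at
quality 0.60, 20 at 0.95) is the adversarial composition on which the
consensus baseline reliably tops out a mediocre decoy while its average
PSS stays below 0.8, so the balanced branch engages;
*easy_high_pss* (one tight cluster at 0.85) lands at or above 0.8 and
exercises the uniform branch; *recoverable* (three clusters) and
*balanced* (two equal clusters) are learnable mixed pools. Cluster
spreads (0.02-0.05) are set so that within-cluster similarity stays
mostly above the 0.5 edge threshold while producing a realistic range of
labels.

What the generator emulates: block-structured similarity, the
quality/centrality inversion of hard targets, noisy-but-informative
single-model scores, correlated secondary metrics. What it does not:
real TM-score geometry (triangle-inequality violations, chain-mapping
artifacts), heavy-tailed score distributions, systematic (non-Gaussian,
decoy-correlated) errors of real single-model scorers, or partial-length
decoys (synthetic decoys are full length, making length normalization a
no-op there). Passing the recovery benchmark therefore shows that the
architecture, sampling and training machinery can learn to combine
single-model and consensus evidence and escape the central-tendency
trap under controlled conditions — not that trained weights transfer to
real CASP pools; for real use the model must be trained on real labeled
pools through the same interfaces.

## Numerical choices and degenerate inputs

* Symmetrization by the arithmetic mean; re-symmetrization is
  idempotent.
* Edge rule is strict (`>` 0.5); the 0.8 sampling boundary goes to the
  uniform branch (`>=`).
* LeakyReLU slope 0.01; layer-norm $\varepsilon = 10^{-5}$; Glorot
  uniform initialization, zero biases, unit layer-norm scales.
* Predicted-score ties at the top rank break toward the smallest decoy
  id; silhouette ties toward smaller $k$; K-means remainder slots go to
  the largest clusters (ties toward the lower cluster index).
* Pools smaller than 2 decoys, non-square matrices, out-of-range
  similarities, duplicate ids, non-numeric scores and unlabeled
  training targets are hard errors; a scorer with no values at all
  imputes 0.5 with an all-ones mask.
* The pool cap is memory-bound only (dense matrices); subgraph tensors
  are built once per sampling pass and reused across epochs.

## Problem sizes in the shipped tests

The test suite exercises oracle equivalence on graphs of up to 10 nodes
over 100+ seeded instances, and method-level recovery on a 40-target
synthetic benchmark (about 200 decoys per target, 200 subgraphs per
target, a 2-layer/2-head model with 16-dimensional node embeddings,
at most 8 epochs) with a stratified 27/3/10 target split — sizes chosen
so the full suite runs on one CPU in minutes while still containing
several adversarial targets in the held-out set. The architecture
defaults (3 layers, 4 heads, 64/32-dimensional embeddings) are sensible
starting points for real pools and are deliberately larger than the
benchmark model.

## Known limitations

Global scores only — no per-residue or interface-level quality.
Upstream similarity matrices and single-model scores are inputs, not
computed here; producing them for large pools is the dominant real-world
cost. Subgraph sampling makes single runs stochastic (seeded and
reproducible); repetition and aggregation shrink, and report, that
variability. The pure-R network is compact; for pools of tens of
thousands of decoys with thousands of subgraphs, expect training runs in
hours rather than minutes.
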