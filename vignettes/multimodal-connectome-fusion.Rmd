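---
title: "Local-to-global multimodal fusion for connectome-based diagnosis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-to-global multimodal fusion for connectome-based diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Case/control classification from resting-state fMRI has to reconcile three
kinds of evidence — functional connectivity between brain regions,
structural (radiomics-style) descriptors of anatomy, and demographics —
while surviving the batch effects of multi-site acquisition. `fusegnn`
implements a hierarchical graph-neural-network approach to this problem:

* a **local ROI network** treats each subject's brain as a graph whose nodes
  are atlas regions (ROIs). A shared-weight bidirectional GRU encodes each
  ROI's BOLD sequence into an embedding `h_e`; a graph generator turns the
  embedding Gram matrix into a learnable adjacency `A = softmax(h_e h_e^T) * n`
  (row-stochastic scaled by the ROI count `n`, which keeps edge-weight
  variance away from zero); a three-layer graph convolution
  `H_k = tanh(D^{-1/2} A D^{-1/2} H_{k-1} W_k)` — each `W_k` a small
  two-layer MLP — propagates Pearson-FC node features over the learned
  graph; and an attention readout (softmax over ROIs of the adjacency row
  sums, scaled by `n`) concatenates attention-weighted node states into a
  per-subject graph embedding, from which a batch-normalized MLP makes the
  local prediction.

* a **global population network** treats subjects as nodes of three graphs:
  functional and structural k-nearest-neighbour graphs (cosine similarity of
  node features, per-node top-k with union symmetrization, `k = 10`), and a
  demographic graph whose edge weights `(cos(MLP(eta_i), MLP(eta_j)) + 1)/2`
  come from a trainable pairwise-association encoder (PAE) evaluated on a
  fixed KNN support. Each channel runs through a **snowball** graph
  convolution block — layer `l+1` consumes the concatenation of *all*
  previous layers, `H_{l+1} = tanh(L [H_0, ..., H_l] W_l)`, with `L` the
  symmetric-normalized adjacency with self-loops — which mitigates the
  oversmoothing that limits plain GCN stacks to a few layers. Nine layers
  are the default depth. Modality-specific blocks have independent weights;
  a modality-common block shares its trunk across channels (each channel
  first passes through a non-shared linear projection to a common width,
  because channels have different input dimensions). Softmax attention over
  the specific embeddings plus the common one fuses them per subject, and an
  MLP classifies.

Training is transductive full-batch node classification: all subjects are
present in the population graphs, and held-out subjects' labels are masked
from every loss term.

# The objective

The total loss is the unweighted sum of four terms:

* **Classification** — cross-entropy of the global head plus
  `lambda = 0.2` times the local head's cross-entropy, so the global task
  dominates.
* **Modality independence** — the Hilbert–Schmidt independence criterion
  `HSIC(H_s, H_c) = (m-1)^{-2} tr(K_c R K_s R)` between each specific
  embedding and the common embedding, with a linear kernel by default
  (cheap, differentiable, and sufficient as an independence penalty; a
  Gaussian kernel with median-heuristic bandwidth is available in the
  numeric API).
* **Modality similarity** — per-channel common embeddings are
  row-normalized, turned into Gram matrices `N = H H^T`, and the Frobenius
  norms of the pairwise Gram differences (functional–demographic,
  functional–structural, demographic–structural) are summed. The
  asymmetric pair list is kept as designed; a full-pairwise variant is a
  flag. Note this term scales with the squared cohort size and therefore
  dominates the raw loss early in training; it decays quickly as the shared
  trunk aligns the channels.
* **Domain** — an adversarial site classifier consuming the fused embedding
  through a gradient-reversal layer (identity forward, gradient negated and
  scaled by `grl_lambda`, default 1), plus the central moment discrepancy
  (CMD) between per-site fused-embedding distributions, orders up to
  `K = 5`, each moment difference scaled by the representation range
  (treated as a constant during differentiation). After every joint update
  the site classifier alone receives `adversary_steps` (default 25) extra
  updates on the current embedding: reversed-gradient training only pushes
  the embedding toward site *confusion* when the adversary is near its
  optimum — with a lagging adversary, maximizing site cross-entropy is
  cheaper to achieve by *anti-encoding* the site (confidently wrong but
  perfectly decodable logits), which a freshly trained probe classifier
  immediately reads back.

Optimization is Adam at learning rate `1e-2`, halved every 100 epochs, for
up to 800 epochs. `two_stage` mode trains the local network alone on its
classification loss, freezes it, and trains the global network on the full
objective minus the local term; `end_to_end` mode optimizes everything
jointly so gradients from the global objective reach the recurrent encoder
and graph generator.

# Site harmonization

Structural features and FC-derived functional features are harmonized with
an empirical-Bayes location–scale model: per-feature least squares
estimates a grand mean, covariate coefficients, and per-site
location/scale; site parameters shrink toward site-level priors (normal on
locations, inverse-gamma on scales, moment-matched) via the standard
conditional iteration. The model is **fitted on training folds only** and
applied to held-out subjects, whose labels never enter the transform — for
that reason the cross-validation harness passes age and sex (not diagnosis)
as preserved covariates; `fit_combat()` accepts any covariate set,
including the label, for transductive use. Subjects from sites unseen at
fit time pass through unchanged with a warning, which is exactly what
happens to the held-out site in leave-one-site-out evaluation.

# The synthetic cohort generator

`cohort_spec()` / `generate_cohort()` produce multi-site cohorts in which
every planted effect is known:

* per subject, a random low-rank-plus-diagonal covariance scaled to unit
  variances; in cases, `edge_effect` (default 0.5) is added/subtracted at
  the planted enhanced/diminished ROI pairs (five of each by default) and
  the matrix is re-projected to positive definite by eigenvalue clipping at
  `1e-6`; the BOLD series is i.i.d. Gaussian with that covariance
  (`32 ROIs x 120 timepoints x 3 sites` by default);
* structural features follow the location–scale site model
  `x = biological mean + gamma_site + delta_site * noise`
  (`gamma ~ N(0, 0.4^2)`, `delta ~ logN(0, 0.2^2)`), so the harmonizer's
  target is correctly specified; informative characters (5 of 10 contiguous
  equal-width blocks over 60 features) get a `0.8` standardized case shift;
* demographics: age `N(34, 11^2)` truncated to `[18, 70]`, sex
  `Bernoulli(0.6)`, education `N(13, 3^2)` with a `0.3` SD case deficit —
  magnitudes chosen to resemble adult psychiatric cohorts; only the
  *relative* group differences matter downstream;
* sites also add per-ROI signal-mean offsets to the time series.

What the generator does **not** emulate: hemodynamic autocorrelation,
scanner-specific spectral content, motion artefacts, heterogeneous series
lengths, or any nonlinear coupling between modalities. Passing tests
therefore demonstrate that the implementation recovers the statistical
structure it models — planted covariance differences, mean shifts, site
location/scale effects — not that the method works on real scanners'
quirks.

# Numerical choices

* Softmax rows are computed with row-max subtraction; cosine similarities
  below zero are clipped before use as propagation weights; KNN ties break
  toward the lowest subject index; edge rankings break ties
  lexicographically by ROI pair.
* The learned adjacency is row-stochastic (rows sum to `n`), hence
  asymmetric; before differential-connectivity ranking it is symmetrized as
  `(M + M^T)/2`, treating connectivity as undirected.
* Degenerate inputs fail loudly: constant ROI rows, zero-norm feature rows,
  single-class folds, empty masks, batch-of-one batch normalization in
  training mode.
* The signal "standardization" step is z-scoring of each ROI's series;
  Fisher's r-to-z applies to correlations and is available separately as a
  flag on `pearson_fc()` (artanh of raw BOLD values would not be
  meaningful).
* In the readout attention, the score vector is the row sums of the learned
  adjacency itself, so ROI attention tracks learned out-strength; the
  per-channel fusion logits `tanh(W H + b)` are reduced to per-node scalars
  by their mean over embedding dimensions; the fusion softmax is per node.
* `p = 0` (no extra output propagation) is the snowball default; `p = 1` is
  a config flag for graphs whose structure carries most of the signal.
* The demographic channel plays the "phenotypic" role in the similarity
  loss's pair list.
* Equal modality weights (summing to 1) combine the per-channel common
  embeddings.

# Desk-scale configuration

The package defaults mirror the reference recipe (recurrent hidden width
32, GCN widths 64-32-16, up to 800 epochs). The test-suite and acceptance
runs use a documented desk-scale configuration chosen to keep a full
5-fold, 300-subject end-to-end experiment within minutes on one CPU:
recurrent hidden 8 (embedding width 16), GCN widths 32-16-8, snowball width
8 with collapse width 16 and output width 16, 12 joint epochs (10-20 local
plus 40-60 global epochs in two-stage runs), and 2-5 folds depending on
the experiment.
Problem sizes per experiment: the planted-effect cohort and the null cohort
use 300 subjects; the regime comparisons (two-stage vs end-to-end, snowball
depth sweep) use 150; the site-effect LOSO contrast uses 120.

# Known limitations

* The local channel on its own is a much weaker classifier than the fused
  model at desk scale: with the small encoder and short schedules above it
  plateaus well below the fused model's accuracy on the default cohort, and
  a ridge classifier on raw FC features outperforms it. The near-uniform
  softmax adjacency at initialization (Gram entries of small random
  embeddings are nearly equal) makes early GCN propagation close to mean
  pooling, so the local model spends much of its budget differentiating the
  adjacency before node information flows usefully. The suite therefore
  verifies the local model's structural contracts and its contribution to
  fusion rather than imposing a standalone performance threshold.
* Transductive evaluation on null (zero-effect) cohorts has graph-correlated
  prediction noise: predictions of test subjects sharing graph
  neighbourhoods are correlated, so the effective sample size behind a
  null AUROC is smaller than the subject count and single-cohort values
  scatter more widely around 0.5 than a binomial intuition suggests. The
  null-calibration check averages over independent null cohorts for this
  reason.
* The modality-similarity loss is an unweighted sum of Gram-difference
  norms and grows with the cohort size; with very large cohorts it would
  dominate the other terms unless per-term weights (exposed in the config
  for ablations) are adjusted.
* Graphs are built once and fixed; only the PAE edge weights are trainable.
  In end-to-end mode the functional KNN graph is built from the harmonized
  FC features plus the *initial* local embeddings, then held fixed while
  the node features continue to evolve.
* No graph sampling or mini-batching: cohorts are limited by full-batch
  memory, which is ample at the hundreds-of-subjects scale the package
  targets.
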