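# fusegnn

Local-to-global multimodal fusion graph neural networks for case/control
classification from functional connectomes, structural feature vectors and
demographics — with a fully synthetic multi-site benchmark, empirical-Bayes
site harmonization, cross-validation harnesses, and interpretation of what
the model learned.

## The problem and the model

Diagnosing a psychiatric condition from resting-state fMRI means combining
evidence that lives at two scales. Within a subject, the ROI×ROI functional
connectivity (FC) matrix — Pearson correlations of BOLD signals — carries
the functional signature; across subjects, similarity in FC, anatomy and
demographics organizes a population in which diagnosis becomes a node
classification problem. `fusegnn` implements a hierarchical model for this:

* **Local ROI network.** Each ROI's standardized BOLD sequence is encoded by
  a shared-weight bidirectional GRU into `h_e ∈ R^{n×d}`; a learnable
  adjacency is generated as `A = softmax(h_e h_eᵀ) · n`; three GCN layers
  `H_k = tanh(D^{-1/2} A D^{-1/2} H_{k-1} W_k)` propagate FC node features
  over it; an attention readout `a_ROI = n · softmax(Σ_j A_ij)` weights and
  concatenates node states into a per-subject graph embedding with a local
  prediction head.
* **Global subject network.** Functional, structural and demographic subject
  graphs (cosine KNN with `k = 10`; a trainable pairwise-association encoder
  for the demographic channel, `W_d(i,j) = (cos(MLP(η_i), MLP(η_j)) + 1)/2`)
  feed 9-layer snowball GCN blocks — each layer consumes the concatenation
  of all previous layers, countering oversmoothing. Modality-specific blocks
  (independent weights) and a modality-common block (shared trunk) produce
  embeddings fused by softmax attention and classified by an MLP.
* **Objective.** `L = L_cls + L_specific + L_common + L_domain`, with
  `L_cls = CE_global + 0.2 · CE_local`, an HSIC penalty
  `(m−1)^{-2} tr(K_c R K_s R)` decorrelating specific from common
  embeddings, a Gram-matrix similarity loss aligning per-channel commons,
  and a domain term combining a gradient-reversal site adversary with the
  central moment discrepancy between per-site embedding distributions.

Everything is trained transductively (held-out labels masked from every
loss), either end-to-end or in two stages, with Adam (lr 1e-2, halved every
100 epochs). Site batch effects in feature tables are removed by an
empirical-Bayes location-scale harmonizer fitted inside training folds
only.

Because real multi-site clinical datasets cannot ship with a package, the
synthetic cohort generator plants known ground truth — strengthened and
weakened ROI-ROI covariance entries in cases, mean-shifted structural
feature blocks, demographic differences, and per-site location/scale batch
effects — so that every downstream claim (classification, edge recovery,
character importance, site-effect suppression) is checkable.

## Worked example

```r
library(fusegnn)

spec <- cohort_spec(n_subjects = 120, n_rois = 16, n_timepoints = 60,
                    enhanced_edges = list(c(1, 5), c(2, 9)),
                    diminished_edges = list(c(3, 7)),
                    n_struct_features = 20, n_characters = 5,
                    informative_characters = c("char_1", "char_2"),
                    seed = 7)
cohort <- generate_cohort(spec)
cohort
#> <cohort_bundle> 120 subjects, 16 ROIs x 60 timepoints, 3 sites
#>   cases: 60, controls: 60
#>   planted: 2 enhanced / 1 diminished edges (effect 0.5), 2 informative characters (effect 0.8)

cfg <- train_config(mode = "end_to_end", epochs = 15, seed = 1,
                    local = local_config(gru_hidden = 8,
                                         gcn_widths = c(16, 8, 4)),
                    global = global_config(snowball_width = 8, c_width = 16,
                                           out_width = 8))
report <- kfold_cv(cohort, cfg, folds = 4)
report
#> <fusegnn_eval> scheme: kfold - 4 folds, 120 evaluated subjects
#>   pooled ACC 0.808 AUROC 0.887 precision 0.836 recall 0.767 F1 0.800

glance(report)       # one-row pooled summary
tidy(report)         # per-fold metrics
autoplot(report)     # calibration curve

# what did the model learn? differential learned connectivity and
# structural-character importance, against the planted ground truth
dfc <- group_differential(average_learned_fc(report), cohort$labels)
top_edges(dfc, k = 2)$enhanced
#> # A tibble: 2 × 5
#>   roi_a roi_b delta  rank direction
#>   <chr> <chr> <dbl> <int> <chr>
#> 1 ROI01 ROI05 0.287     1 enhanced
#> 2 ROI02 ROI09 0.208     2 enhanced

mask_character_importance(report, cohort, top_k = 2)
#> # A tibble: 5 × 6
#>   character auroc_masked auroc_unmasked auroc_drop  rank top
#>   <chr>            <dbl>          <dbl>      <dbl> <int> <lgl>
#> 1 char_2           0.759          0.888    0.129       1 TRUE
#> 2 char_1           0.858          0.888    0.0292      2 TRUE
#> 3 char_3           0.891          0.888   -0.00361     3 FALSE
#> 4 char_5           0.905          0.888   -0.0172      4 FALSE
#> 5 char_4           0.908          0.888   -0.0206      5 FALSE
```

The pooled AUROC says how well held-out subjects are ranked by their
predicted case probability. The `top_edges` table lists the strongest
case-minus-control differences in the *learned* ROI adjacency — here the
two planted enhanced connections (ROI01-ROI05, ROI02-ROI09) rank first.
The character table reports the AUROC drop when each structural feature
block is zeroed at inference: the two planted informative blocks are the
two flagged as most contributive. Numbers above were produced by this
exact code (seeds included); a different BLAS may change trailing digits.

A thin command-line driver for simulate/train/evaluate/interpret workflows
lives at `inst/cli/fusegnn.R`. The methods vignette
(`vignettes/multimodal-connectome-fusion.Rmd`) documents the model,
numerical choices and limitations in detail.

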