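# idrgraph

Joint per-residue prediction of protein intrinsic disorder and six
disordered functions — protein-, DNA-, RNA-, ion-, lipid-binding and
flexible linker — from per-residue embeddings, for researchers studying
intrinsically disordered regions (IDRs) and their functional roles.

Disordered functions are statistically dependent: the same residue is
often annotated with several of them. `idrgraph` quantifies that
dependence with the pairwise information gain

IG(X, Y) = H(X) + H(Y) − H(X, Y)   (bits),

the entropy saved by predicting labels X and Y jointly rather than
separately, and builds it into the model: after a bidirectional GRU
context encoder and a globally attending GRU produce a hidden vector
h_i per residue, six ReLU layers map h_i to node features X_i^(n) of a
fully connected six-node functional graph whose trainable adjacency is
initialized from the IG matrix. A graph convolution aggregates
Y_i^(n) = ReLU((Σ_m A_nm X_i^(m)) W′^(n) + b′^(n)), disorder is read
from the elementwise max over the six nodes, and seven sigmoid heads
emit per-residue propensities. Training minimizes the joint binary
cross-entropy over the seven heads with analytic gradients (verified
against finite differences); decision thresholds are calibrated by
maximum F1. Layer-wise relevance propagation (αβ-rule) attributes any
head's logit back onto the functional graph's nodes and edges, and a
CAID-style metric battery (AUC, AUPR, APS, Fmax, MCC, BACC, pooled and
per-protein, plus multifunctional-residue evaluation and a paired
bootstrap predictor comparison) evaluates the results. A seeded
synthetic generator with controllable label co-occurrence makes every
component testable at desk scale without downloads.

## Worked example

Simulate a correlated six-function dataset, estimate its IG matrix,
train a small model and evaluate it:

```r
library(idrgraph)

cfg <- sim_config(n_proteins = 16L, length_range = c(40L, 60L),
                  density = 0.12, cooccurrence = 0.15,
                  embed_dim = 12L, snr = 5, seed = 7)
sim <- simulate_dataset(cfg)

ig <- ig_matrix(sim$labels)
round(unclass(ig)[1:3, 1:3], 3)
#>                 protein_binding dna_binding rna_binding
#> protein_binding           0.720       0.004       0.001
#> dna_binding               0.004       0.570       0.019
#> rna_binding               0.001       0.019       0.540

ids <- names(sim$embeddings)
mcfg <- gim_config(embed_dim = 12L, bigru_hidden = 12L,
                   attn_hidden = 12L, node_dim = 8L, seed = 7)
tcfg <- train_config(learning_rate = 1e-2, batch_size = 4L,
                     max_epochs = 120L, patience = 120L, seed = 7)
model <- train_gim(sim$embeddings[ids[-(1:4)]], sim$labels[ids[-(1:4)]],
                   sim$embeddings[ids[1:4]], sim$labels[ids[1:4]],
                   mcfg, tcfg)
glance(model)
#> # A tibble: 1 × 4
#>   epochs_run best_epoch best_val_loss n_parameters
#>        <int>      <int>         <dbl>        <int>
#> 1        120         17         0.483         4575

profiles <- lapply(ids, function(id)
  gim_forward(sim$embeddings[[id]], model$params, protein_id = id))
names(profiles) <- ids
evaluate_predictions(profiles, sim$labels, threshold_vector(model$thresholds))
#> # A tibble: 7 × 10
#>   label             auc  aupr   aps  fmax   mcc  bacc threshold n_pos n_neg
#>   <chr>           <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>     <dbl> <int> <int>
#> 1 disorder        0.848 0.855 0.856 0.860 0.602 0.807    0.723    484   325
#> 2 protein_binding 0.809 0.603 0.604 0.557 0.398 0.749    0.0910   161   648
#> 3 dna_binding     0.737 0.282 0.288 0.420 0.300 0.704    0.181    109   700
#> 4 rna_binding     0.852 0.607 0.609 0.577 0.521 0.724    0.454    100   709
#> 5 ion_binding     0.778 0.343 0.345 0.514 0.391 0.749    0.190    141   668
#> 6 lipid_binding   0.838 0.595 0.596 0.617 0.419 0.773    0.192    132   677
#> 7 linker          0.857 0.553 0.556 0.695 0.560 0.775    0.407    184   625
```

The IG diagonal holds each label's entropy in bits; off-diagonals are
pairwise information gains (a co-occurrence of 0.15 at these densities
yields couplings of a few millibits to ~0.02 bits). The metric tibble
reports, per head, the threshold-free ranking metrics and the binary
metrics at the calibrated thresholds. At this deliberately small scale
(12 training proteins) the returned minimum-validation-loss model — its
best epoch was 17 of 120 — generalizes but underfits; the methods
vignette discusses why, and the 40-protein pipeline study reaches
per-head training AUC above 0.86.

Attribution of one residue's prediction onto the functional graph — here
the residue with the highest protein-binding propensity of the first
protein:

```r
prof <- gim_forward(sim$embeddings[[ids[1]]], model$params,
                    protein_id = ids[1], traces = TRUE)
explain_residue(prof, model$params, residue = 49, head = "protein_binding")
#> <relevance_map> SYN0001 residue 49, head 'protein_binding' (logit -1.8850)
#> protein_binding     dna_binding     rna_binding     ion_binding
#>         -1.1683         -0.1225         -0.3955         -0.1886
#>   lipid_binding          linker
#>         -0.0050         -0.0039
```

Node scores sum each node's share of the seeded (here negative) logit;
an edge's score is the sum of its two node scores.

A thin command-line wrapper with subcommands `simulate`, `ig`, `train`,
`predict`, `evaluate`, `compare` and `explain` is installed at
`inst/cli/idrgraph` (run it with `Rscript`); every run writes a JSON
manifest with its seed, configuration and input checksums.

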