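---
title: "idrgraph: model, statistics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{idrgraph: model, statistics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Intrinsically disordered regions (IDRs) are protein segments without a
stable tertiary fold. They are not inert: disordered residues bind
proteins, DNA, RNA, ions and lipids, and act as flexible linkers between
structured domains. A single disordered residue frequently carries more
than one of these roles, and the roles are statistically dependent — a
residue annotated as protein-binding is far more likely than chance to
also be lipid-binding. `idrgraph` implements a per-residue joint
predictor of intrinsic disorder and the six disordered functions that
exploits exactly this dependence, together with the statistics
(information gain), attribution machinery (layer-wise relevance
propagation) and evaluation battery (CAID-style metrics) that surround
it.

The package is desk-scale by design: the embedding interface accepts
vectors from any external protein language model, and a seeded synthetic
generator produces datasets on which every component — training
included — runs in minutes on one CPU.

## Labels and coordinates

Seven binary per-residue labels in a fixed column order: `disorder`,
`protein_binding`, `dna_binding`, `rna_binding`, `ion_binding`,
`lipid_binding`, `linker`. Region annotations are 1-based inclusive
(DisProt convention) in all files and all user-facing tibbles. Residues
not covered by any region of a label are treated as negatives for that
label; an optional per-residue mask is supported throughout (loss,
calibration, evaluation) for the case where unannotated residues should
instead be ignored, but the default is all-observed. This mirrors
training corpora built by discarding proteins whose functional regions
lack disorder annotation rather than masking.

## Functional correlation as information gain

For two binary function labels $X$ and $Y$ with residue-pooled empirical
distributions, the information gain

$$\mathrm{IG}_{XY} = H(X) + H(Y) - H(X,Y)$$

is the number of bits saved by predicting the pair jointly rather than
separately — the mutual information. We read the "information required
for individual prediction" as the sum $H(X)+H(Y)$ over the two separate
predictions; this makes IG symmetric, nonnegative, and bounded by
$\min(H(X), H(Y))$, the data-processing bound the package enforces and
property-tests. (A strict upper bound of 1 bit holds only for
non-degenerate binary labels that are not perfectly correlated;
perfectly co-occurring fair-coin labels attain exactly their common
entropy, which the bound above accommodates.)

Two estimation choices were genuinely open and are fixed as follows:

* **Pooling unit is the residue.** All residues of all training
  proteins are pooled before estimating marginals and pairwise joints,
  because the labels, the loss and the metrics are all residue-level.
  Averaging per-protein IG values would weight short proteins up for no
  statistical reason.
* **The matrix diagonal stores $H(X)$** rather than being undefined, so
  the serialized 6×6 object carries the marginal uncertainty of each
  label alongside the pairwise gains. Graph initialization uses only the
  off-diagonals plus a constant self-loop.

## The model

Per protein, the forward pass is:

1. **Context encoding.** A bidirectional GRU over the per-residue
   embedding rows $r_1,\dots,r_L$ produces $P$ ($L \times 2H$); the two
   directions are run over the sequence and its reversal and
   concatenated.
2. **Global attention GRU.** A left-to-right GRU with zero initial
   state; at step $i$ the context $c_i = \sum_j \alpha_{ij} p_j$ is a
   softmax-weighted sum over *all* residues with scores
   $s_{ij} = h_{i-1}^\top W_a p_j$. Attention is global, not causal: the
   recurrence is ordered, but every $c_i$ sees the whole sequence.
3. **Function feature mapping.** Six ReLU layers map $h_i$ to node
   features $X_i^{(n)} \in \mathbb{R}^F$, one per function.
4. **Graph interaction.** Each residue owns a fully connected six-node
   graph whose trainable adjacency $A$ is initialized from the IG matrix
   (off-diagonals) with unit self-loops. The graph convolution
   aggregates $Y_i^{(n)} = \mathrm{ReLU}\big((\sum_m A_{nm} X_i^{(m)})
   W'^{(n)} + b'^{(n)}\big)$. The aggregation index is resolved as a
   standard 6-node GCN applied independently per residue — the target
   node $n$ receives messages from every node $m$ weighted by $A_{nm}$;
   because the kernel belongs to the target node, the sum vectorizes as
   $(\sum_m A_{nm} X^{(m)}) W'^{(n)}$.
5. **Disorder pooling.** $Y_i^{\mathrm{IDR}}$ is the elementwise maximum
   of the six aggregated node features (ties route to the
   lowest-indexed node for gradient and relevance purposes).
6. **Heads.** Seven sigmoid heads: disorder reads
   $Y_i^{\mathrm{IDR}}$, function $n$ reads $Y_i^{(n)}$. All scores are
   strictly inside $(0,1)$.

A sequence-only ablation (`gim_forward_seq()`) removes step 4: heads
read the mapped features directly and disorder max-pools them. Both
variants share every other parameter, so graph-vs-sequence comparisons
are paired.

The adjacency is initialized symmetric but is *not* constrained to stay
symmetric or nonnegative during training; only its initialization is
specified by the IG statistics.

### Dimensions and defaults

`gim_config()` defaults (`bigru_hidden = 128`, `attn_hidden = 128`,
`node_dim = 32`) suit 1024-dimensional external protein-language-model
embeddings. The synthetic desk-scale studies in this package use
`embed_dim = 12`, `bigru_hidden = 24`, `attn_hidden = 24`,
`node_dim = 16`: large enough that capacity is not the binding
constraint on the synthetic task (larger settings fit no better in our
sizing runs), small enough that a 200-epoch training run on 20 proteins
of 40–60 residues takes about two to four minutes on one CPU core. The
end-to-end pipeline study uses a smaller model (`bigru_hidden = 12`,
`node_dim = 8`) on 40 proteins with learning rate 5e-3, sized so the
whole simulate–estimate–train–predict–evaluate–explain chain, run
twice to verify bit-reproducibility, stays within a coffee break.
These sizes are package choices, stated here so that they can be
revised coherently.

### Training

The loss is the joint binary cross-entropy: per head the BCE (natural
log, scores clipped to $[10^{-7}, 1-10^{-7}]$) averaged over unmasked
residues, then averaged over the seven heads (uniform head weights by
default; configurable). Optimization is Adam (authored in the package,
on the flattened parameter vector) with a global gradient-norm clip of 5
for recurrent stability. Defaults: learning rate $10^{-3}$, batch of 8
proteins, early-stopping patience 20 epochs; the desk-scale synthetic
studies use learning rate $10^{-2}$ and batch 4, which converged
fastest in our sizing runs. Variable-length proteins are handled by
per-protein gradient accumulation within a batch — mathematically the
padded-and-masked batch loss, without materializing padding. The
returned parameters are those with minimum *validation* loss, never the
final epoch, and the whole run is reproducible from the two seeds
(initialization and shuffling/dropout).

Every gradient path — through the heads, max-pool routing, graph
convolution, feature maps, the attention coupling ($h_{i-1}$ enters both
the GRU and the attention scores) and both GRU directions — is analytic
and verified against central finite differences to $10^{-4}$ relative
error in the test suite.

Decision thresholds are calibrated per head by exhaustive F1 sweep over
the observed validation scores (positive when score ≥ threshold, ties
broken toward the larger threshold); a head whose calibration data
contain a single class falls back to 0.5 with a warning.

### What the desk-scale training runs do and do not show

On the synthetic study conditions (20 proteins, signal-to-noise 5,
co-occurrence 0.15), 200 epochs bring the training loss from ≈0.64 to
≈0.15 nats (roughly 75% reduction) with per-head training AUC
0.95–0.98. The residual loss is not a capacity or data problem — a
linear probe on the raw embeddings separates the labels almost
perfectly — but an optimization property of the architecture itself:
per-residue information reaches the heads only through the globally
attended context $c_i$, so the attention must *learn* to localize
before residue-resolved fitting becomes possible, and within 200 epochs
it does so only partially. We report this honestly rather than altering
the architecture: the near-complete (≥90%) loss reductions that a
directly connected per-residue model would reach are not attained by
the attention-bottlenecked architecture at this scale. The bottleneck
is also visible in the boundary residues of functional regions, which
dominate the residual loss.

Generalization behaves as expected for a high-capacity sequence model
on few proteins: with a genuinely held-out validation split the
validation loss reaches its minimum within a few dozen epochs and then
rises, so the returned (minimum-validation-loss) parameters are earlier
and less fitted than the final epoch. The pipeline study uses 40
proteins, at which point the best-validation model reaches training
AUC above 0.85 on every head; with fewer than ~20 proteins, expect the
returned model to underfit the training set noticeably.

## Layer-wise relevance propagation

`lrp_linear()` implements the $\alpha\beta$-rule: the relevance of each
output unit is redistributed over its inputs proportionally to the
positive contributions $w^+_{jk} h_j$ (weight $\alpha$) minus the
negative contributions (weight $\beta$), with denominators stabilized by
a sign-matched $10^{-9}$. The package requires $\alpha - \beta = 1$
(conservation convention) and defaults to $\alpha = 1, \beta = 0$;
$\alpha=2,\beta=1$ is available. Relevance is seeded with the explained
head's *pre-sigmoid logit* — standard LRP practice that keeps
conservation meaningful, since the sigmoid output is not additive over
contributions.

Propagation runs through the head layer and, for disorder, through the
max-pool (winner-take-all routing), then through the graph convolution
viewed as one linear map from the concatenated node features, and stops
at the six mapped node features $X^{(n)}$: the object being explained is
the functional-correlation unit, not the recurrent encoder. Node
contribution scores sum the relevance over a node's features; the score
of an edge is defined as the sum of its two endpoint node scores, hence
symmetric by construction. Dataset-level importance sums these maps over
true-positive residues of the explained head.

With $\alpha=1,\beta=0$ and zero biases, total relevance is conserved
through every propagated layer (property-tested); a layer whose
contributions to some output are all negative absorbs that output's
relevance — an intentional property of the positive-only rule, noted
rather than patched.

## Evaluation battery

* **AUC** is computed as the Mann–Whitney statistic (ties half-credit).
* **AUPR** trapezoidally integrates the precision–recall curve over the
  observed thresholds; **APS** is the step-sum
  $\sum_k (R_k - R_{k-1}) P_k$. Both treat tied scores as one operating
  point.
* **Fmax** is the exhaustive maximum F1 over observed scores, ties
  toward the larger threshold — identical, by construction and by test,
  to the threshold calibrator.
* **MCC** uses the convention 0 when any denominator factor vanishes;
  **BACC** is the mean of sensitivity and specificity.
* Pooled evaluation concatenates residues across proteins; per-protein
  evaluation averages within-protein metrics over proteins containing
  both classes for the head.
* **Multifunctional (MF) residues** — residues with ≥2 true function
  labels — are grouped by their exact label set. A residue of a type is
  correct only if *every* involved head calls it positive. For the
  threshold-free Fmax of a type we need a scalar score per residue; the
  package uses the minimum of the involved heads' propensities, the
  conservative reduction consistent with the all-heads-positive AND.
* **Predictor comparison** uses a paired bootstrap over proteins
  (resample unit = protein, default 1000 draws, seeded) of the pooled
  AUC difference, with the add-one two-sided p-value. A bootstrap was
  chosen over analytic AUC variance estimates for generality across the
  metric battery.

## Synthetic data generator

The generator emulates the statistical structure the model is built to
exploit, not protein realism:

* Sequences are uniform over the 20 canonical amino acids — sequence
  composition deliberately carries no signal, so encoder tests stay
  orthogonal to sequence content.
* Per function label, contiguous regions are placed by a Poisson count
  with geometric lengths (memoryless, one parameter) at a configured
  expected coverage (default 0.12 per label).
* Pairwise label co-occurrence: each placed region of label $x$ spawns
  an overlapping region of label $y$ with probability $c_{xy}$
  (symmetric matrix, default 0.15 in the smoke study), which is what
  makes the empirical IG matrix controllable. Infeasible settings
  (expected coverage above 1) are rejected.
* Disorder is the union of all functional residues plus independent
  disorder-only regions — functions annotate disordered regions, never
  ordered ones.
* Embeddings: one orthogonal unit signature per label, summed over a
  residue's active labels, plus isotropic Gaussian noise of standard
  deviation $1/\mathrm{SNR}$ (default SNR 5, at which a linear probe
  recovers each label at AUC > 0.95 — verified in the tests).

What passing tests on this generator do **not** show: robustness to the
long-range compositional signals, annotation noise, label sparsity
imbalances and length distributions of real curated corpora. The
generator validates the machinery (estimation, optimization,
attribution, evaluation), not biological performance claims.

## Numerical choices and degenerate inputs

* $0 \log 0 := 0$ in every entropy; probabilities validated to sum to 1
  within $10^{-9}$.
* IG clipped at 0 to absorb floating-point rounding; serialization uses
  C99 hex-float literals so write/read round-trips are bit-exact.
* Binarization tie rule everywhere: score ≥ threshold is a positive
  call. Prediction files round-trip scores at their printed 4-decimal
  precision.
* Checkpoints are single-file RDS containers (config, parameters,
  thresholds, the IG matrix used at initialization, package version) and
  round-trip bit-exactly.
* Degenerate metric inputs error early (single-class AUC) or follow
  stated conventions (MCC 0, threshold 0.5 fallback).
* Proteins longer than 30,000 residues are rejected outright rather
  than windowed, matching the upstream exclusion of such chains.
* Max-pool ties route to the lowest node index, making gradients and
  relevance deterministic.

## Known limitations

* Training is pure-R linear algebra: ample for the desk-scale studies
  (minutes), not for corpus-scale training against real embeddings.
* LRP stops at the mapped node features; attribution through the
  recurrent encoder to individual embedding coordinates is out of
  scope.
* The attention-GRU information bottleneck discussed above limits how
  completely the model can fit residue-resolved labels in few epochs.
* The bootstrap comparison assumes proteins are exchangeable; it does
  not model within-protein residue correlation beyond the protein-level
  resampling.
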