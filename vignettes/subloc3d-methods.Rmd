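---
title: "Knowledge-enhanced subcellular localization from 3D volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-enhanced subcellular localization from 3D volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(subloc3d)
```

## The problem

A tagged protein imaged by 3D confocal microscopy produces single-cell
two-channel volumes: a DNA/nucleus reference channel and the protein
channel. The task is multi-label classification of the protein's
subcellular localization (nucleoplasm, nucleolus, cytoplasm, membrane,
vesicles, ER, Golgi, focal adhesions, cell contact, ...). Real screens of
this kind have three structural difficulties that drive every design choice
in this package:

* **Class imbalance** — localization classes differ by more than an order
  of magnitude in how many proteins display them.
* **Weak annotation** — labels exist per *protein*, and are copied onto
  every cell of that protein even though individual cells, by
  heterogeneity, may not display every labeled pattern.
* **Protein-level generalization** — train/validation/test splits are made
  at the protein level, so the classifier is always evaluated on proteins
  it has never seen.

## Model

### Dual-branch encoder with adaptive gating

Each volume is encoded twice: a 3D residual stack consumes the volume
itself, and a mirrored 2D residual stack consumes its maximum-intensity
z-projection. Each residual block is
conv(3^d, stride 2) - batchnorm - ReLU - conv(3^d) - batchnorm, with a
1x1 convolution on the skip path (stride 2) and ReLU after the addition;
channels double per block, capped at eight times the base width. Global
average pooling after the last block yields one feature vector per branch.
The stated full-scale depth is six blocks for 128 x 128 inputs; an input
must satisfy `spatial dim >= 2^n_blocks`, so the desk-scale volumes used
throughout the tests (12 x 32 x 32) run three blocks.

The branches are fused by adaptive gating: with `z = [f3d; f2d]`,
`g = sigmoid(W_g z + b_g)` elementwise, the pre-fusion feature is
`g * f3d + (1 - g) * f2d`, and a fully connected layer maps it to the
768-dimensional fused feature. The gate lets the model decide, feature by
feature, whether depth information or the cleaner planar view is more
reliable.

Two heads sit on the fused feature: a sigmoid multi-label classification
layer over the concatenation of the fused feature with an adapted protein
knowledge feature (zeros when no knowledge is available), and a softmax
protein-ID head over the training proteins.

### Classification loss: asymmetry and confidence weights

The classification loss for class `j` with prediction `p` and label `y` is

```
L_j = alpha_j * [ -y log p - (1 - y) * (p^-)^r * log(1 - p^-) ],
p^- = max(p - m, 0)
```

averaged over classes (and the batch), with focusing exponent `r = 4` and
probability margin `m = 0.05`. The asymmetric negative term removes easy
negatives from the gradient entirely (hard threshold `m`) and down-weights
the rest (soft threshold `r`), so the abundant negative labels of a
multi-label problem cannot drown the scarce positives. The confidence
weights `alpha` map per-class annotation grades to 1.0 / 0.5 / 0.1 for
grades 3 / 2 / 1: a subtle, weakly supported annotation contributes little,
which is exactly the right behaviour when protein-level labels are copied
onto cells that may not display the pattern. Negative classes take
`alpha = 1` (grades only annotate positives). All logarithms are natural
and clamped at `1e-12`, so the loss is finite on the closed unit interval.

### Knowledge module: joint image-KGE training

Protein/GO knowledge enters as a graph of (head, relation, tail) triples:
protein -> GO annotations and GO -> GO structural relations, with entity
categories (protein, CC, MF, BP) and a free-text annotation per GO term.
Graphs are first filtered to the tagged-protein subgraph: protein-GO
triples keep only tagged heads, and a GO-GO triple survives only when both
GO terms are related to strictly more than two tagged proteins through the
kept protein-GO triples. The rule is idempotent and drops orphan entities.

GO embeddings are initialized from annotation text. The default text
encoder is a deterministic character-trigram feature hasher (64-d, signed
buckets, L2-normalized) followed by a learned linear adapter into the
entity space; a pre-trained biomedical text encoder can be plugged in
behind the same two-field interface (`dim`, `embed`). The hasher keeps the
test path free of any heavyweight pre-trained dependency while preserving
the property that matters here: distinct annotation texts get distinct,
reproducible vectors.

Four scoring functions are implemented, each with analytic gradients:
TransE `||h + r - t||`, RotatE `||h o r - t||` with unit-modulus complex
rotations, PairRE `||h o rH - t o rT||`, and ComplEx
`-Re<h, r, conj(t)>` (negated so that *lower = more plausible* across all
four). PairRE follows its original formulation in which entity embeddings
are constrained to the unit sphere: the constraint is enforced where
embeddings are created and updated (text initialization, the projection
step after each optimizer update, and the normalization of the adapted
protein feature), and the score uses its inputs as given. This choice —
rather than re-normalizing inside the scoring function — is what makes
exact head inversion possible, and head inversion is load-bearing (below).

The knowledge-embedding loss for a triple is the contrastive form

```
L_KE = -log sigmoid(gamma - d_pos) - mean_i log sigmoid(d_neg_i - gamma)
```

with category-aware negatives: a corrupted tail is drawn uniformly from
the *other* entities of the true tail's category, so negatives are
plausible enough to be informative. The margin `gamma = 6` and
`n = 8` negatives are desk-scale defaults (the source method states
neither); both are configuration keys.

During joint training the protein entity of a sampled triple is not a
free embedding: it is the current cell's fused image feature passed
through a linear protein adapter (and projected to the unit sphere for
PairRE). Gradients of `L_KE` therefore flow through the adapter into the
encoder, which is the mechanism by which the image module "learns protein
information". Up to `k = 4` of the cell's protein-GO triples are sampled
per step.

At prediction time no cell-derived protein entity exists for an unseen
protein, so the protein knowledge feature is recovered from the graph
alone: for each protein-GO triple, solve `d(h, r, t) = 0` for the head
(`t - r` for TransE, inverse rotation for RotatE, `(t o rT) / rH` for
PairRE) and average the implied heads. ComplEx admits no exact inverse;
its feature pools the rotated-back tails `t o conj(r)` in the same
real/imaginary layout (a documented surrogate, kept at full entity
dimension so the adapter is method-agnostic). Proteins without triples get
a zero vector and an `absent` flag, and the classifier falls back to the
image-only path. Averaging implied heads (rather than raw tail embeddings)
is the default because it is the reading under which the pooled feature
actually estimates the protein's own entity representation; raw-tail
pooling is a one-line variant.

### Protein-ID aggregation

Cells of one protein should look alike to the encoder. The ID head is
trained with the single-label asymmetric loss (`r_id = 4`, `m_id = 0.1`)
against the cell's protein identity, but only for cells whose labels
intersect the nine low-variability localization classes (cytoplasm,
nucleoplasm, nucleolus, focal adhesions, cell contact, membrane, ER,
vesicles, Golgi); classes with high intra-class morphological variability
would make the objective counterproductive. The gate is implemented as a
per-cell mask on the loss rather than a dataset filter — the two are
equivalent in effect, and masking keeps batch composition untouched.

The total objective is `1.0 * L_SLC + 0.1 * L_KE + 0.1 * L_ID`.

## Synthetic data generator

The generator is first-class, tested code that emulates the *structure* of
an endogenous-tagging screen rather than its optics. Each cell is a
jittered ellipsoid with a concentric nuclear ellipsoid; the nucleus
channel is the filled nucleus; the protein channel is a mixing-weighted
sum of per-class renderers on geometrically defined supports (uniform
nucleoplasm; 1-3 nucleolar spheres; cytoplasm minus nucleus; a thin
boundary shell for membrane; cytoplasmic puncta for vesicles; a
perinuclear band for ER; a single juxtanuclear blob for Golgi; bottom-slice
boundary puncta for focal adhesions; a lateral boundary patch for cell
contact), plus an additive background with Gaussian jitter and optional
Poisson shot noise on scaled intensities (200 expected photons at unit
intensity).

Protein label sets are drawn from configurable class frequencies (skewed
frequencies reproduce class imbalance); a protein becomes multi-label with
probability 0.3 (a second draw adds a third class). Per cell, mixing
weights are drawn from a sorted, normalized Gamma(2) vector, so secondary
patterns are genuinely fainter than primary ones. Weak annotation is
emulated by dropping a labeled pattern from a given cell with the
configured probability while keeping the label. Confidence grades derive
from the realized weight (>= 0.7 -> 3, 0.3-0.7 -> 2, else 1), mirroring
prominent / clearly detectable / subtle-and-weak annotation practice
without claiming equivalence; a dropped pattern has weight 0 and thus
grade 1, which is exactly the situation the confidence weights exist for.

The companion knowledge-graph generator creates one CC term per
localization class plus distractor MF/BP terms, `located_in` triples per
labeled class (optionally corrupted), random protein-MF/BP triples, a
small `is_a` hierarchy, and a deterministic template text per GO term.
With zero corruption the CC triples predict the labels perfectly — the
oracle condition for knowledge-enhancement experiments.

What the generator does **not** emulate: optics (no PSF, no anisotropic z
blur), morphological diversity beyond random ellipsoid axes, cell-cycle
state, or correlated annotation noise. Passing tests on this generator
demonstrate that the estimation machinery works under the stated
structural difficulties — not that the model reaches any particular
accuracy on real microscope data.

Default desk-scale volumes are (z, y, x) = (12, 32, 32) so that the full
pipeline trains in minutes on one CPU; all sizes are configuration keys.

## Numerical and implementation choices

* Tensors are column-major `(channel, spatial..., batch)`; convolutions
  run as im2col gathers into a per-sample cache-resident buffer followed by
  BLAS `dgemm` (C++), with zero-padding folded into the index plan as a
  sentinel. Backward passes recompute the gather rather than caching the
  column matrix for the whole batch — memory locality wins over
  recomputation at these sizes.
* Inputs are normalized per cell and channel: a square-root
  variance-stabilizing transform (photon noise scales with signal) followed
  by min-max scaling to [0, 1]; constant channels map to 0. Prediction is
  therefore invariant to per-cell intensity scale.
* Batch-norm uses batch statistics in training and running averages
  (momentum 0.9) at inference; running statistics are carried alongside the
  optimizer's parameter tree, not inside it.
* Optimization is Adam (lr 1e-3 default). Cosine decay, decoupled weight
  decay on weight matrices, random y/x flips, a multi-label mixup, and a
  nucleus-gated third input channel are all available as configuration
  keys but default off: each was evaluated on the synthetic benchmark and
  none reliably improved held-out accuracy (mixup clearly hurt — blending
  two cells' nucleus geometries confuses the reference channel).
* The margin cases of the losses (`p <= m`) are exactly zero by
  construction, not approximately; gradient code treats them as inactive.
* Ties in average precision break by stable sort on descending
  probability; an MCC denominator of zero scores 0 by convention; macro
  metrics average over classes with at least one positive unit in the
  evaluated set (a class absent from a small held-out protein set carries
  no information about the classifier).
* Hard calls threshold probabilities at 0.5; image-level evaluation
  averages per-cell probabilities per source image before thresholding.
* `split_by_protein` uses floor + largest-remainder so 100 proteins at
  70/15/15 give exactly 70/15/15; a cell-level mode covers datasets whose
  proteins map one-to-one to classes.

## Problem sizes used by the test suite

The test suite and the acceptance script run entirely on simulated data at
sizes chosen so the whole pipeline is exercised end to end in minutes:
the generalization benchmark uses 30 proteins x 20 cells at (12, 32, 32)
and 10 epochs; the knowledge-enhancement comparison makes two classes
visually identical through the renderer-alias mechanism while their GO
triples stay distinct (the comparison studies use the nucleus-gated input
encoding, which suits their smaller volumes); the weak-annotation comparison sets a 20% dropout
rate and compares the asymmetric confidence-weighted loss against plain
cross-entropy on the same seeds; the ID-aggregation comparison measures
mean within-protein cosine similarity of fused features with and without
the ID loss. Held-out macro-MCC on these synthetic conditions sits in the
0.5-1.0 range depending on the seed's draw of test proteins — a handful of
held-out proteins whose faint secondary patterns (mixing weight near the
grade-1 band) are intrinsically hard make the lower end of that range, a
variance any protein-level split of this size carries.

## Known limitations

* The encoder is deliberately small; no attention, no VAE variants.
* Knowledge features are recomputed per epoch (embeddings move during
  joint training) and treated as constant inputs within an epoch;
  classification gradients do not flow into GO embeddings — only the
  knowledge-embedding loss moves them.
* The hashing text embedder carries no semantics — only identity and
  reproducibility. Synonymous annotation texts get unrelated vectors.
* One protein entity per cell (the current cell's adapted feature) rather
  than a memory bank; a memory-bank EMA variant is a natural extension.
* Nucleus centers for cropping are inputs; no segmentation is attempted.
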