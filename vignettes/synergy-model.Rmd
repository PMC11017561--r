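---
title: "Predicting drug-drug synergy with permutable multi-view fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-drug synergy with permutable multi-view fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-throughput combination screens measure how strongly a drug pair acts on
a cancer cell line beyond the expectation under non-interaction. Two label
conventions dominate: the Loewe score, obtained by evaluating a
four-parameter sigmoid dose-response curve
$(R_{\min} + R_{\max}\,((x_A+x_B)/m)^\lambda)\,/\,(1 + ((x_A+x_B)/m)^\lambda)$
at the combined dose (`loewe_score()`), and the ComboScore, the sum of
observed minus expected growth fractions over a concentration grid
(`combo_score()`). Because the score depends on the doses only through their
sum, `loewe_score(p, a, b)` equals `loewe_score(p, a + b, 0)` exactly — the
sham-combination property — and the package tests both identities.

Measured screens cover a vanishing fraction of the pair-by-cell-line space,
so the practical task is regression: given two drug structures and a
cell-line profile, predict the continuous synergy score, and rank the
unmeasured trios.

## The model

Each drug is encoded three ways:

* **MACCS keys** — 166 predefined substructure bits (computed via OpenBabel;
  the conventional unused leading bit of toolkit arrays is dropped so key
  *i* sits at position *i*);
* **HashTT** — hashed topological torsions: every linear path of four
  bonded heavy atoms, labelled by element, pi electrons and out-of-path
  branching, canonically oriented and hashed into `n_bits` buckets;
* **MAP4** — MinHashed atom pairs: circular substructures of radius 1 and 2
  bonds around each atom of a pair, combined with their topological
  distance, MinHashed with a fixed universal hash family and folded modulo
  `dims` into presence bits.

A cell line is its gene-expression vector and binary mutation vector over a
landmark gene panel.

One subnetwork per fingerprint kind processes a trio. Every input sequence
runs through a three-layer one-dimensional convolutional encoder (channel
widths 8/16/32, window 3, stride 1, symmetric zero padding so the length is
preserved at every layer, GELU after each layer), is flattened and affinely
projected to a shared feature dimension $D$. The two drugs of a pair share
one encoder per subnetwork — both carry the same fingerprint kind, and the
pair is semantically unordered — while expression and mutation have their
own encoders. The four resulting feature vectors are stacked into a
$4 \times D$ view tensor.

Fusion uses two **permutable MLP blocks**. A block applies a residual MLP
along the feature axis, $H + \mathrm{LN}(\mathrm{Swish}(H W^1_D) W^2_D)$,
transposes the tensor, applies the analogous residual MLP along the view
axis, and transposes back, so information is mixed alternately across
features and across the four views. With the branch weights at zero a block
is the exact identity — a property the test suite asserts bit-for-bit, and
the mechanism behind the fusion-free ablation. The fused tensor is
flattened, projected to a hidden width $\hat D$ with a GELU in between, and
reduced to a synergy feature of length $\tilde D$; a two-layer GELU head
turns it into a scalar score. The final prediction is the arithmetic mean
of the three subnetwork scores, and training minimizes the mean squared
error against the measured labels.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `channels` | 8, 16, 32 | convolution channel widths (fixed by the architecture) |
| `kernel` | 3 | convolution window (tokens); any odd width works |
| `n_bits`, `dims` | 512 | HashTT / MAP4 fingerprint lengths |
| `d`, `d_hat`, `d_tilde` | 64, 256, 64 | feature, fusion-hidden and synergy-feature widths |
| `head_hidden` | `d_tilde / 2` | prediction-head hidden width |
| `lr`, `batch_size` | 1e-4, 128 | Adam learning rate and mini-batch size |
| `epochs`, `patience` | 500, 20 | epoch cap and early-stopping patience |
| `val_frac` | 0.1 | inner validation fraction used for early stopping |

The channel widths and the two fusion blocks are structural; the remaining
sizes are free. We size the reference configuration (512-bit hashed
fingerprints, $D = 64$) so that a full training run on the reference
synthetic study finishes in about a minute and a half on one CPU core;
doubling every width is a constructor argument away and changes no code
path. Labels are standardized with training-fold statistics inside
`train_model()` (predictions are mapped back), which makes the Adam step
size independent of whether scores arrive on a Loewe-like or
ComboScore-like scale. Layer norm uses $\varepsilon = 10^{-5}$; weights use
fan-in uniform initialization under a recorded seed; biases exist on every
affine map but the block equations hold with them at zero. No dropout or
weight decay is applied by default.

Numerical notes: GELU is computed exactly via the Gaussian CDF (`erfc`),
not the tanh approximation, so unit tests can compare against
`x * pnorm(x)` at 1e-12; gradients are hand-derived and verified against
central finite differences to relative error below 1e-4 on a tiny
configuration; training is bit-reproducible for a fixed seed under
single-threaded BLAS, and checkpoints restore bit-identical predictions.

## Evaluation protocol

`holdout_split()` reserves 10% of the records as an independent test set.
On the remaining 90%, `make_split_plan()` builds 5-fold plans under three
strategies: *random* (records shuffled into folds), *leave-cell-out* (the
cell-line set is partitioned, so test cell lines are never seen in
training) and *leave-combination-out* (the set of unordered drug pairs is
partitioned, so both orderings of a pair stay together). Fold disjointness
is audited by brute force in the tests. Metrics are RMSE, the standard
coefficient of determination $R^2 = 1 - \mathrm{SSE}/\mathrm{SS_{tot}}$,
and Pearson's correlation; `run_cv()` reports the per-fold mean and the
pooled-prediction metrics side by side, since the aggregation convention is
a free choice. Expression is re-standardized per fold on the training cell
lines only, to avoid leakage.

A note on $R^2$: a variance written without the $1/n$ factor would make the
ratio $\mathrm{RMSE}^2/\mathrm{Var}$ dimensionally inconsistent; the
package uses the standard coefficient of determination, which all baseline
tools report.

`run_ablation()` reproduces the architecture variants: dropping fingerprint
subnetworks (the remaining heads are averaged), replacing both fusion
blocks by the identity, or swapping every convolutional encoder for an
affine + GELU feedforward stack of matched output dimension.
`noise_study()` trains on profiles perturbed by multiplicative
($x \cdot N(1,\sigma)$) or additive ($x + N(0,\sigma)$) Gaussian noise —
mutation vectors are noised as real vectors, deliberately leaving
$\{0,1\}$ — and reports the correlation between noisy-trained and
clean-trained predictions on a common test set; each cell line draws from
its own seed substream so extending the panel never disturbs existing
draws. The noise levels are a required argument: no particular
$\sigma$ grid is canonical. `rank_unmeasured()` enumerates and sorts the
unmeasured trios with lexicographic tie-breaking.

## What the synthetic generator emulates — and what it does not

`generate_synergy_dataset()` builds a self-contained study: drugs sampled
from a packaged vocabulary of 63 real, pre-validated small-molecule SMILES;
expression profiles i.i.d. $N(0,1)$; mutations i.i.d. Bernoulli(0.1);
labels from a planted function
$w_d \langle u, f_i + f_j\rangle + w_c \langle v, e_c\rangle +
w_i \langle r, f_i \odot f_j\rangle + \varepsilon$
on the MACCS bits and the expression profile, rescaled to mean 0 and sd 20
to mimic screening score magnitudes. MACCS is used for label construction
so the oracle stays independent of the configurable HashTT/MAP4 lengths.
The reference conditions are 20 drugs, 10 cell lines, 500 records and label
noise sd 5; the effect weights default to $(1, 1, 1)$, giving the cell-line
term roughly half the signal variance and the drug terms the rest; 128
genes per profile keep the encoders honest without inflating run time.

The generator emulates the *shape* of a combination screen, not its
biology: expression has no covariance structure, mutations carry no signal,
the planted function is linear-plus-interaction rather than mechanistic,
and with 10 cell lines entity-level effects are coarse. Passing tests
therefore demonstrate that the pipeline recovers plantable structure and
respects its contracts — not that it predicts real synergy. A corollary
worth stating: with so few distinct cell lines, *any* smooth model's
predictions contain a cell-line component, and the correlation between two
essentially arbitrary 10-level effects is heavy-tailed, so null-model
correlations (e.g., after permuting labels) fluctuate far more than the
nominal $1/\sqrt{n}$ would suggest. The test suite measures this null
explicitly.

## Problem sizes used by the checks

The test suite trains on desk-scale instances: the reference 500-record
study for signal recovery (one 80/20 fold, three seeds), 64 records for the
overfit-capacity check (the first logged epoch loss is the initialization
MSE because a 64-record set fits in one batch), and a 200-record subset
with a narrow model for the noise study. `scripts/acceptance.R` re-runs the
headline computation — generation, 90/10 hold-out, default training,
independent-test metrics, permuted-label null and overfit ratio — from
scratch against the installed package.

## Known limitations

* Fingerprints are this package's own implementations of the torsion and
  MinHashed atom-pair schemes; they satisfy the documented invariants
  (determinism, graph-invariance, length contracts) but are not bit-compatible
  with other toolkits' implementations.
* Aromatic perception follows OpenBabel's kekulized output; pi-electron
  counts derive from bond orders.
* The regression target is a single continuous score; classification-style
  synergy calls are out of scope.
* Training is single-threaded by design for reproducibility; the
  architecture is intentionally compact rather than tuned for accuracy on
  any real screen.
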