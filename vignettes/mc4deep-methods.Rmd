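---
title: "Methods: deep hybrid prediction of 4mC sites in mc4deep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep hybrid prediction of 4mC sites in mc4deep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

N4-methylcytosine (4mC) is a DNA modification in which a methyl group is
attached to the N4 position of cytosine. It is abundant in prokaryotes
(host/foreign DNA discrimination, restriction–modification systems) and
detectable in some eukaryotes by SMRT sequencing kinetics. Genome-wide
experimental mapping is expensive, so sequence-based classifiers are used to
decide, for a fixed-length window centred on a cytosine, whether that
cytosine is a 4mC site. `mc4deep` implements such a classifier for 41-bp
windows (configurable); both classes carry a central C — positives were
kinetically called modified, negatives were not — so the signal lies in the
flanking context, not in the centre base.

## The model, stage by stage

**1. Quality filtering.** Windows can carry a SMRT modification quality
value (modQV). The conventional threshold for calling a position modified is
30, and `filter_by_modqv()` defaults to the protocol's literal rule of
dropping samples with modQV above 30. That rule reads inverted relative to
the threshold's meaning (a *higher* modQV is stronger evidence of
modification), so the opposite direction is available via
`mode = "drop_below"`; we default to the rule as printed and expose the
switch. Redundancy removal is exact-duplicate removal by default, with an
optional hook for a CD-HIT binary (80% identity) when one is installed; the
built-in fallback is deliberately weaker and says so in its log line.

**2. Preliminary encodings.** Eight classical feature encodings map a
window to a numeric vector. The literature that introduced these encodings
specifies the families but rarely every constant, so the exact formulation
is pinned here:

| scheme  | content | length (L = 41) |
|---------|---------|------------------|
| BKF     | per-position one-hot (4L) + relative k-mer frequencies, k = 2, 3, 4 | 500 |
| DBPF    | per dinucleotide position: 16-bit one-hot + running frequency | 680 |
| KNN     | fraction of positive labels among the nearest 2%, 4%, ..., 20% of references (per-position identity similarity, ties by reference order) | 10 |
| PCP     | six B-DNA dinucleotide step parameters (twist, tilt, roll, shift, slide, rise; crystallographic averages adapted from Olson et al. 1998, standardized over the 16 dinucleotides) per position | 240 |
| MMI     | mutual-information terms f(xy)·ln(f(xy)/(f(x)f(y))) over the 10 unordered adjacent pairs, plus pointwise interaction-information terms over the 20 unordered adjacent triples; any zero marginal gives 0 | 30 |
| PseDNC  | pseudo dinucleotide composition, λ = 3 correlation tiers, weight w = 0.1, correlation from the six PCP scales | 19 |
| PseEIIP | (sum of EIIP values of the trinucleotide) × its relative frequency; EIIP A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335 | 64 |
| RFHCP   | per position: ring / hydrogen-bond / amino-group bits + cumulative frequency of the position's own base | 164 |

The BKF k-mer range was chosen so that the BKF vector has length exactly
500, matching the published input shape of the extractor network
(1 × 500 × 1). The RFHCP density channel is the running frequency of the
*current* base among the prefix; it is bounded in (0, 1] but not monotone
along the sequence (the base identity changes position to position), which
is why the tests assert its defining computation rather than monotonicity.
KNN features are label-derived, so dataset-level KNN encoding requires a
fold assignment and computes every row from references *outside the row's
fold*; the same folds are reused by all later stages.

**2-mer note on MMI.** The "standard three-way extension" is taken to be
the pointwise interaction information
f(xyz)·ln(f(xy)f(xz)f(yz)/(f(x)f(y)f(z)f(xyz))), weighted by the triple
frequency, which reduces to the pairwise form's structure and is zero
whenever any involved frequency is zero.

**3. Advanced features (CNN + BLSTM).** Each encoding is fed to its own
small network: `[Conv1D → ReLU → MaxPool] × 3 → bidirectional LSTM →
flatten → dense(ReLU) → sigmoid`. Protocol constants (defaults of
`network_config()`): 3 conv blocks with 16/32/64 filters of length 8,
pooling 2, 5 training epochs, three-fold cross-validation. The sigmoid
output probability is the scheme's *advanced feature*; out-of-fold values
form the n × 8 advanced matrix that downstream stages train on, and a
refit-on-all-rows model per scheme serves new samples (whether the original
protocol refits after CV is unstated; we do, and keep out-of-fold values
for training features).

Convolutions use valid padding, with pooling after every block, giving
timesteps 500 → 246 → 119 → 56 for BKF. A published intermediate shape of
223 timesteps is not derivable from these hyperparameters under any common
padding convention, so the package documents its own shape table instead.
Unspecified training constants are pinned from the published sweep lists:
Adam with learning rate 0.001, batch size 64, dropout 0.2 (on the flattened
recurrent output), LSTM width 32 per direction with concatenated
directions, dense width 16. Alternate conv depths 2–7 are supported via
`n_conv_layers` to mirror the depth experiment.

Three encodings are shorter than the minimal input of the default stack
(57): KNN (10), PseDNC (19) and MMI (30). The pipeline caps the depth per
scheme to the deepest feasible stack — the leading blocks of the configured
one — giving depth 1 for KNN/PseDNC and 2 for MMI. `build_network()` itself
refuses an infeasible configuration and reports the minimal length, so the
capping is an explicit, logged pipeline policy, not silent behaviour.

The extractors are implemented from scratch in RcppArmadillo (im2col+GEMM
convolutions, full backpropagation-through-time for both LSTM directions,
Adam, inverted dropout, own mt19937 RNG). The test suite includes a
finite-difference gradient check of the complete stack; training is
bit-deterministic for a fixed seed on a fixed BLAS.

**4. Integrated algorithm (iterative probability stacking).** Six
classical learners — k-nearest neighbours (k = 5), logistic regression, an
RBF SVM (cost 1, γ = 1/d, probability outputs), Gaussian naive Bayes, a
decision tree and a 100-tree random forest — compete on the current
matrix. Each learner is scored by out-of-fold accuracy over the same
folds; the winner's out-of-fold class-1 probability column is appended
(f9, f10, ...) and the widened matrix is the next round's input. Iteration
stops when the winning accuracy changes by less than `tol` (default 1e-4)
or after `max_iter` (default 10) rounds; five rounds grow the 8-column
matrix to 13 columns. The winner is selected by cross-validated accuracy
(the protocol's headline metric; whether the original selection used
training or CV accuracy is unstated). Appended columns are out-of-fold so
later iterations and the final classifier never train on leaked labels;
for new samples, each round's winner is refit on the full training matrix
and the refits are applied in sequence.

**5. Final classifier.** A small fully connected network on the enriched
matrix: two ReLU hidden layers (32, 16 by default; 2–4 layers supported)
and a sigmoid output. Training constants (50 epochs, batch 32, Adam 0.001,
early stopping on a 10% validation split with patience 5, threshold 0.5
with the boundary counted positive) are unspecified by the protocol and
pinned here as package defaults. When the validation split would hold
fewer than 50 samples, the early-stopping point is driven by noise rather
than generalization — the stopping epoch then varies wildly with the seed —
so the net trains its full epoch budget instead; early stopping engages
only at dataset sizes where the split is informative.

**6. Metrics.** SN = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/n,
MCC = (TP·TN − FP·FN)/√((TP+FN)(TP+FP)(TN+FP)(TN+FN)) with the 0/0 case
defined as 0, and AUC by the Mann–Whitney rank statistic with ties counted
½ (identical to the exhaustive pairwise estimator; verified against it and
against pROC in the tests).

## Evaluation protocol

One stratified fold assignment (seeded shuffle within class, round-robin
deal; default k = 3) is shared by every stage. All training-time features
(advanced columns, stacking columns) are out-of-fold, and the final
classifier is itself evaluated out-of-fold over the same folds, so
`run_pipeline()`'s reported metrics are leakage-free held-out estimates.
Leakage is asserted by instrumentation in the tests: every stage records
the training row indices of every fold model, and the suite checks that no
row's probability was produced by a model trained on its fold.

## The synthetic benchmark

Real 4mC corpora derive from SMRT kinetics on specific genomes and are not
redistributable here, so the package ships a seeded generator instead.
Negatives are i.i.d. draws from a configurable background composition
(uniform by default); positives additionally carry a position-weight-matrix
motif adjacent to the central C. The PWM gives the consensus base
probability 0.25 + 0.75·effect per motif position (others uniform), so
`effect = 0` makes classes identical (a true null) and `effect = 1` plants
a deterministic word; the motif's KL divergence from background is a
closed-form monotone function of `effect` (`motif_kl()`). The consensus
word is fixed and composition-biased, as real methylation motifs are —
a composition-balanced word would make the composition-only encodings
(MMI, PseDNC, PseEIIP) blind to it by construction. Defaults: motif width
8, starting 2 positions right of the centre; synthetic modQV values
(|N(20, 15)| shaped) decorate half the samples so the filtering stage is
exercisable.

What this emulates — and does not. The generator produces exchangeable
windows with a single planted motif at a fixed offset. Real data have
positional heterogeneity, composition skew, near-duplicate windows,
class imbalance (real corpora are roughly 2:1 positive:negative) and
label noise from kinetic calling. Passing the synthetic tests therefore
demonstrates that the machinery is correct, calibrated under the null and
able to recover a planted signal — not that any particular accuracy will
transfer to a real genome.

## Problem sizes and numerical choices

Simulation studies in the test suite and acceptance script use n = 2000
(1000/1000) for the null-calibration and strong-motif runs and n = 600 for
the effect-monotonicity sweep, with the reduced `profile = "fast"` network
(filters 4/8/16, LSTM 12, dense 8) — sizes chosen to keep a full
cross-validated 8-encoding study at desktop scale while leaving the
protocol defaults untouched and asserted separately. Other choices:
probabilities are clamped to [1e-7, 1-1e-7] inside the cross-entropy;
accuracy ties between learners go to the first in the fixed order
(knn, logistic, svm, nb, tree, rf); distance ties in KNN go to the earlier
reference; the forget-gate bias is initialized at 1; Glorot-uniform init
elsewhere; one master seed fans out to fold assignment, weight
initialization, shuffling, dropout and every seeded learner.

## Known limitations

- Exact-duplicate removal is weaker than 80%-identity clustering; with a
  CD-HIT binary configured the original protocol's filter is available.
- The KNN encoding and learner are transductive (they carry their
  references); serialized models therefore include the training windows.
- Training determinism holds for a fixed BLAS/platform; across BLAS
  builds, floating-point reduction order may differ, which is why
  behavioural tests use tolerance bands rather than frozen floats.
- No probability calibration of the final sigmoid outputs is attempted,
  and multi-species transfer is out of scope.
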