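---
title: "Methods: water-drop feature selection and a backpropagation classifier for emotion text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water-drop feature selection and a backpropagation classifier for emotion text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emodrop)
```

`emodrop` classifies the emotion expressed in short health-related texts
(six classes: Angry, Sad, Fear, Excited, Bored, Happy by default). This
vignette is the package's account of its methods: the model and its
assumptions, the parameters that matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate,
and the numerical and design choices that were genuinely open.

## 1. The pipeline and its assumptions

The pipeline is `clean → vectorize → split → resample → select → train →
evaluate`, orchestrated by `run_pipeline()`. Its core assumptions:

* **Bag-of-n-grams sufficiency.** Emotion signal is carried by the
  presence and frequency of specific terms; word order beyond the n-gram
  window is ignored. Default features are unigram counts — raw counts,
  not TF-IDF, because counts make both the wrapper fitness and the
  network's behavior directly auditable (TF-IDF is available via
  `weighting = "tfidf"`).
* **Severe class imbalance.** The reference corpus shape has a 61:1
  ratio between largest and smallest class. Resampling
  (`resample_classes()`) equalizes class counts, and is applied to
  *training rows only, after* the stratified split: resampling first
  would copy duplicated rows into the test set and overstate accuracy.
* **One look at the test set.** The 20% stratified split
  (`stratified_split()`) is held out through feature selection and model
  selection; both of those use resampled training data and internal
  validation carved from it.

## 2. Text cleaning

Five steps in a fixed order: lowercase, punctuation→space,
tokenization, stop-word removal, common-term removal, rare-term removal.
Two choices deserve justification:

* **Punctuation becomes a space, not nothing**, so `"end.start"` yields
  two tokens rather than a fused artifact.
* **Step order**: the frequency filters run after stop-word removal so
  their document-frequency and count statistics describe content words.
  The order of the two corpus-level filters between themselves is
  immaterial (they act on disjoint tails of the frequency spectrum).

Parameters, with units and defaults:

| parameter | meaning | default | rationale |
|---|---|---|---|
| `common_df_threshold` | document-frequency fraction above which a term is removed | 0.90 | standard corpus-linguistics convention for "appears nearly everywhere" |
| `rare_min_count` | minimum total corpus count to keep a term | 3 | removes terms seen once or twice, where noise overwhelms signal |
| `stopword_list` | function words removed | packaged English list | shipped as plain text so nothing is downloaded at run time |

Documents that end up empty are retained as empty token vectors: labels
must stay aligned with the corpus's class counts. The chain is
idempotent on its own output (tested).

## 3. Intelligent Water Drops feature selection

### 3.1 The dynamics

Feature selection is a wrapper search over size-`m` subsets, run by
`iwd_select()`. The search graph has one node per feature plus a
virtual start node; every edge carries *soil*. One drop per tour starts
at the start node with velocity `init_vel` and makes `m` moves:

* **Transition**: from node *i*, probability of an unvisited *j* is
  `f(s_ij) / Σ_k f(s_ik)` with `f(s) = 1/(ε_p + g(s))`, where `g`
  shifts candidate soils so the most negative becomes zero. Lower soil,
  higher probability.
* **Velocity update**: `v ← v + a_v / (b_v + c_v · s_ij²)`.
* **Soil erosion**: traversal time `t = HUD(j) / v`; the drop removes
  `Δs = a_s / (b_s + c_s · t²)` and the edge is updated
  `s ← (1 − ρ_n)·s − ρ_n·Δs` (both orientations; the table is
  symmetric). Soil may go negative; the `g`-shift in the transition
  rule is what keeps probabilities well defined.
* **Global reinforcement**: after each iteration of `n_drops` tours,
  the iteration-best tour (by fitness) has each of its edges updated
  `s ← (1 + ρ_IWD)·s − ρ_IWD · carried_soil/(m − 1)` (divisor guarded
  at 1 when `m = 1`), and the best-so-far subset is replaced only on a
  strict improvement, so the recorded best fitness is non-decreasing.

`HUD(j)` — heuristic undesirability — is a label-aware prior cost.
Point-biserial correlation is a two-class statistic, so for K classes we
compute it against each one-vs-rest indicator, take the maximum absolute
association per feature, normalize over features to [0, 1], and set
`HUD = 1 − association`, floored at 0.05 so traversal times stay
positive.

### 3.2 The wrapper fitness

`fitness = mean stratified 3-fold accuracy of a nearest-centroid
classifier on the subset's columns − λ·|subset|/n_features` (λ = 0.01).
Nearest centroid was chosen over the network itself because the search
evaluates hundreds of subsets; the network is trained once, on the final
subset. A flag (`fitness_fn`) allows network-in-the-loop selection for
fidelity experiments.

**Duplicate-aware folds.** After oversampling, the training matrix
contains exact duplicate rows. If duplicates can land in different
folds, cross-validation rewards *memorizing* them — in our measurements
random 30-feature subsets scored 0.46 instead of their honest 0.36, and
the planted signal was no longer separated from background. The fold
assignment therefore groups rows with identical feature vectors into
the same fold. The same principle governs the network's validation
split (§4).

### 3.3 Constants, and why two defaults are not the canonical ones

Defaults: `a_v = a_s = 1`, `b_v = b_s = 0.01`, `c_v = c_s = 1`,
`ρ_n = ρ_IWD = 0.9`, `init_vel = 200`, `ε_p = 0.01` — the canonical
water-drop settings. Two quantities had to be re-derived because, at
this problem's scale, the canonical values make the heuristic guidance
numerically inert:

* **`hud_scale` (default `10·init_vel·√(b_s/c_s)` = 200).** The erosion
  term is sensitive to traversal time around `t* = √(b_s/c_s)` = 0.1.
  With unit-range HUD and velocity 200, `t ≈ 0.005` and `c_s·t² ≈
  2.5·10⁻⁵`, invisible against `b_s = 0.01`: every edge would erode
  identically and the class-association prior would do nothing. Scaling
  HUD so times straddle `t*` makes desirable edges erode ~100× more
  soil than undesirable ones.
* **`init_soil` (default 100).** After one traversal the edge soil is
  `(1 − ρ_n)·s₀ − ρ_n·Δs`. For the erosion difference (up to
  `ρ_n·a_s/b_s = 90`) to be visible, the decayed initial soil
  `(1 − ρ_n)·s₀` must be on the same scale — hence s₀ = 100. At the
  often-quoted s₀ = 10000, first traversals all look alike and the
  search reinforces whatever random trail forms first (measured: planted
  keyword recovery stuck at 16%, end-to-end accuracy 0.59).

Budget defaults: `n_drops = 10`, `n_iterations = 100` (a few hundred
node-visits per feature on a ~600-feature problem; seconds to a minute
of wall time). `stagnation_reset` (default off) re-initializes the soil
table after a stalled stretch while keeping the best subset — useful on
*small* graphs, where strong erosion makes the first trail absorbing;
on large graphs the budget is better spent deepening trails. The subset
size `m` defaults to 10% of the features (at least 5, at most all)
since no principled value exists without domain knowledge.

### 3.4 Known limitation: recall vs. fitness

On strong-signal corpora the fitness saturates: subsets mixing some
planted keywords with correlated background terms classify as well as
the full planted set. Elitism therefore has no gradient toward full
keyword recall — typical recall of the planted 30 keywords is 0.35–0.5
even when test accuracy exceeds 0.9. The selection is a *predictive*
subset, not a *causal inventory*; tests assert the former.

## 4. The backpropagation network

A three-layer perceptron, sigmoid activations in both the hidden and
output layer, one output unit per class with one-hot targets:

```
h = σ(W₁ᵀx + b₁),  o = σ(W₂ᵀh + b₂)
```

* **Loss.** Gradients descend `½Σ(o − t)²`, whose minimizer coincides
  with the RMSE minimizer; RMSE is what is logged, used for early
  stopping, and used to pick the hidden size — the quantity a reader of
  the training log sees is exactly the quantity being optimized for.
  `bpnn_backward()` is verified against central finite differences
  (relative 10⁻⁶), the module's central oracle.
* **Optimization.** Per-sample gradient descent with momentum
  (defaults: learning rate 0.1, momentum 0.9, ≤500 epochs), sample
  order reshuffled each epoch under the seed; a `full_batch` mode takes
  one mean-gradient step per epoch. Weights start uniform in
  `±1/√fan_in`, biases at zero.
* **Input standardization** (default on). Raw n-gram counts reach 20+;
  at those magnitudes sigmoid units saturate and gradients vanish.
  Inputs are z-scored with training-set statistics (sd floored at
  10⁻⁸), stored in the model and re-applied at prediction.
* **Validation and early stopping.** A stratified, duplicate-aware
  split (default 20% of training rows) drives early stopping (patience
  20) and snapshotting: the returned model is the epoch with the best
  validation RMSE. On data too small to carve a validation set the
  training RMSE is used instead. Hidden-size selection trains one model
  per grid value (default {4, 8, 16, 32, 64}) on the same split and
  keeps the smallest size at the minimum validation RMSE. The held-out
  test split plays no role in any of this.
* **Prediction** is the argmax over output activations, ties to the
  lowest class index — deterministic and permutation-consistent.

## 5. The synthetic corpus generator

`generate_corpus()` emulates the statistical structure the pipeline
assumes, not language. Each document of class *c* draws tokens i.i.d.:
with probability `keyword_rate` from class *c*'s disjoint pool of
`keywords_per_class` keywords; with probability `numeric_token_rate` a
random digit string (exercising the numeric-token counting path);
otherwise from a shared background vocabulary with Zipf (1/rank)
weights — realistic frequency structure that exercises both the
common-term and rare-term filters. Document lengths are shifted
Poisson; labels are then flipped uniformly with `label_noise_rate`.

Defaults state the world the package is benchmarked in: six classes at
the published 1343/358/742/1215/22/522 imbalance (scaled by
`default_table1_spec(scale)`, floored at 2 documents per class so every
class survives a stratified split), 5 keywords per class, keyword rate
0.35, background vocabulary of 500 words, numeric rate 0.05, mean
length 60 tokens (floor 5), label noise 0.05. Keyword rate and noise
are the signal/noise compromise under which a correct pipeline lands
near, but not trivially above, the 90% accuracy mark; document length
and vocabulary size are typical of short clinical free-text notes.

What a green test on this generator does **not** establish: robustness
to correlated features, topic drift, spelling variation, class-
conditional document length, or any linguistic phenomenon — token draws
are i.i.d. by construction. The background alphabet deliberately
excludes the letters *k* and *w* so the `kw` marker inside planted
keywords is unambiguous ground truth.

## 6. Numerical choices and degenerate inputs

* Sigmoid is computed branch-wise (positive and negative arguments
  separately), stable for |x| up to several hundred.
* Transition probabilities: soils are shifted by the most negative
  candidate before inversion; `ε_p = 0.01` guards the division.
* Metric conventions: any 0/0 ratio (a class never predicted and never
  present) is reported as 0 and flagged `undefined` — degenerate
  classes are surfaced, not hidden. Macro averages are unweighted class
  means; overall accuracy is trace/total.
* Vocabulary order is lexicographic (radix sort, locale-independent),
  making every matrix — and therefore every downstream number —
  bit-identical across runs and platforms.
* One global seed drives everything. Stage seeds derive from it by
  hashing the stage name (`stage_seed()`), so any stage can be rerun in
  isolation; all RNG use is wrapped so the caller's RNG state is
  restored.
* Ties: nearest-centroid and argmax prediction break toward the lowest
  class index; equal-RMSE hidden sizes resolve to the smaller network;
  equal-fitness subsets keep the incumbent.

## 7. Open design points, resolved

* **Which resampling direction?** Both are provided; oversampling is
  the pipeline default because undersampling a 61:1 corpus discards
  almost all majority-class data.
* **Analysis with and without the minority class** is supported via
  `drop_minority_class`, which removes the smallest class before
  modeling.
* **Macro vs. weighted averaging** of per-class metrics: macro
  (unweighted), matching the single-summary-bar presentation the four
  metrics are usually given, and the harsher choice under imbalance.
* **Common/rare filtering order relative to stop words** is not fixed
  by any external constraint; filters run on stop-word-free text so
  their statistics describe content words.
* **The velocity rule's symbols.** The update implemented is the
  canonical `v + a_v/(b_v + c_v·s²)`; the occasionally-seen opaque
  renderings of this rule (an undefined `q` over `b_v + c_v·s²`) are
  mapped onto `a_v` and the edge soil.

## 8. Limitations

* The IWD selection is predictive, not an inventory of the true signal
  features (§3.4).
* A two-document class cannot be learned: its single training row is
  duplicated by oversampling, and the duplicate-aware validation split
  deliberately refuses to validate on copies of it. Its per-class
  metrics will read 0 with the `undefined` flag — by design.
* Per-sample training in pure R is fast enough for hundreds of
  documents and tens of features (the regime after selection), not for
  vocabulary-scale inputs; run the selector first, or use
  `batch_mode = "full_batch"`.
* No stemming, lemmatization, embeddings or hashing features; the
  cleaning chain and bag-of-n-grams are the modeled scope.
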