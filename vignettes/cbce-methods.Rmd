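---
title: "Cluster-based classifier ensembles: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based classifier ensembles: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbce)
```

## The model

Activity recognition from ambient sensors is treated here as classification
of pre-segmented instances: each instance is the multiset of sensor
activations recorded while one activity of daily living was performed. The
core assumption is that an activity is characterised by *which* sensors it
touches (and possibly how often), not by the order in which they fire; both
encodings the package offers — per-sensor counts ("numeric") and per-sensor
presence ("binary") — discard order entirely.

An ensemble member is not a conventional classifier but a *cluster
collection*: k-means is run on the training set with the Euclidean metric
restricted to a random feature subset, and each retained cluster is
summarised by a full-dimension centroid plus its per-class membership
counts $N_{ij}$. The support matrix converts counts to scores in $[-1, 1]$
against the even-mixture benchmark $N_i/M$:

$$A[i,j] = \begin{cases}
 \dfrac{N_{ij} - N_i/M}{N_i - N_i/M} & N_{ij} \ge N_i/M\\[1ex]
 \dfrac{N_{ij} - N_i/M}{N_i/M} & \text{otherwise.}
\end{cases}$$

Both branches are linear in $N_{ij}$, agree (at 0) at the crossing point,
and pin the extremes: $1$ for a pure cluster, $-1$ for an absent class.
Because the subsets are random, mixed clusters are expected and the
benchmark makes support relative to the cluster's own size.

Classification fuses the ensemble's nearest clusters exponentially.
Classifier $k$ selects its closest cluster $i_k$ at full-space distance
$d_k$ and contributes $\exp\!\big(A_k[i_k,j]\,/\,(1+d_k)\big)$ to class $j$,
except that $A = -1$ ("no member of this class at all") contributes exactly
0 rather than $e^{-1/(1+d)}$: absence is treated as exclusion, not weak
evidence. The $1+d$ scaling means proximity amplifies whatever the cluster
says — positive support grows as $d \to 0$, negative support becomes a more
confident veto. The class with the largest total wins.

A note on the fusion rule's form: written inline, the expression is
ambiguous between $e^{A}/(1+d)$ and $e^{A/(1+d)}$. The bundled worked
example resolves it — the hand-checked values ($e^{0.3/2.7} = 1.12$,
$e^{0.4/2} = 1.22$) are only consistent with the exponent-of-ratio form,
which the package uses throughout.

## Parameters

* **K, ensemble size** (default 30). A single collection's accuracy is at
  the mercy of one random subset/cluster-count draw; averaging over K draws
  stabilises it. `stability_experiment()` measures exactly this: the
  standard deviation of test accuracy over repeated retrainings falls
  steeply from K = 1 and has flattened by K ≈ 30, which is why 30 is the
  default. Larger K buys little and costs linearly.
* **Cluster-count bound** (default multiplier 3). Each collection draws its
  cluster count uniformly from $[M, 3M]$. The lower bound allows one
  cluster per class; the upper bound limits empty clusters without
  preventing them — empty clusters at convergence are dropped, since they
  have no members to define either a centroid or a support row.
* **Encoding and centroid mode.** Binary encoding with mode centroids is
  the default for binary data (every centroid coordinate is then 0/1);
  numeric data uses mean centroids. On data where the same activity
  produces widely varying counts (a fridge opened once or five times),
  numeric distances scatter instances of one class apart, and binary
  encoding classifies measurably better; the test suite reproduces
  this direction on synthetic high-count-variance data, and the
  Davies–Bouldin index of the class grouping moves the same way.
* **Feature subsets.** Size uniform on $1..L$, positions drawn with
  replacement. Duplicate positions are collapsed before clustering —
  keeping them would double-weight a dimension in the metric with no
  stated semantics — but the raw draw is recorded. Subsets are *not* tuned
  per classifier: randomisation is the diversity mechanism, and tuning
  each member on the training set would overfit.

## Determinism and numerical choices

* All randomness flows from one master seed; per-classifier and per-fold
  sub-seeds are drawn through the seeded RNG (kept below $2^{31}$), so
  training, cross-validation and simulation are bit-reproducible.
* k-means: Lloyd's algorithm; initial centroids are P distinct instances
  sampled uniformly; single run, no restarts; assignment ties go to the
  lowest cluster index; a cluster emptied mid-iteration keeps its previous
  centroid until convergence; iteration stops when assignments are stable
  or after 100 iterations.
* The per-feature mode used for binary centroids resolves an exact
  half-half tie to 0 (no activation).
* With a single class the above-average branch of the support formula is
  degenerate ($N_i - N_i/M = 0$); support is defined as 1, every cluster
  being pure by construction.
* Supports are kept at full precision internally; display rounding is
  half-away-from-zero (`round_half_up()`), matching hand-computed tables
  rather than banker's rounding.
* Classification distance is *root* Euclidean in the full feature space
  against full-dimension centroids; the per-classifier subspace matters
  only during clustering. A squared-distance utility exists for
  illustration but is never used in fusion.
* A query whose fused support is zero for every class (possible only in
  pathological hand-built models) falls back to the training majority
  class; prediction ties resolve to the earlier class in the model's class
  order.
* Model files are JSON with 17 significant digits, which round-trips IEEE
  doubles exactly; a reloaded model predicts identically.

## Evaluation protocol

Cross-validation is stratified (round-robin within class, seeded), since
the datasets of interest are heavily imbalanced; with any class smaller
than the fold count it falls back to a plain shuffled split with a
warning. Both common accuracy summaries are reported — the mean of
per-fold accuracies and the pooled-confusion trace/total — because they
differ slightly when folds are unequal. Confusion matrices are oriented
predictions-in-rows, actuals-in-columns; precision is therefore
diagonal/row-sum and recall diagonal/column-sum, macro-averaged without
class weights (again: imbalance). A class never predicted has undefined
precision; it is reported as 0 with a warning rather than NA so macro
averages stay defined. The Davies–Bouldin index uses mean
member-to-centroid distance as scatter and errors on coincident centroids,
where the ratio is undefined.

## The synthetic generator

`generate_instances()` emulates the structure of single-resident
smart-home recordings: each activity is a template of per-sensor
activation probabilities, activated sensors fire a geometric number of
times (geometric because repeat interactions — a fridge opened again — are
memoryless-ish and overdispersed), events are emitted in random order, and
optional noise fires out-of-template sensors. `default_smarthome_config()`
instantiates 14 named sensors and 7 activities with realistic imbalance
(toileting dominating at 112/245, dinner preparation rare at 10/245) and
overlapping kitchen signatures: breakfast and dinner preparation share the
fridge, plates cupboard and groceries cupboard, while dinner additionally
reaches the freezer and pans cupboard with larger occurrence counts.
`signature_templates()` builds block-structured templates with a
controllable overlap fraction for controlled experiments, from fully
disjoint (labels perfectly recoverable) to fully exchangeable pairs.

What the generator does *not* model — and therefore what passing tests do
not establish about real data: temporal day structure and activity
durations, sensor malfunction or annotation error beyond uniform noise,
interleaved or concurrent activities, and any order information within a
segment (deliberately absent, since the encodings cannot see it). Results
on the synthetic benchmark demonstrate correctness of the machinery and
the qualitative behaviour of the method, not field performance.

## Problem sizes in the test suite

The suite trains hundreds of small ensembles; sizes were chosen so the
checks are statistically meaningful while the whole suite stays quick:
synthetic datasets of 60–350 instances over 8–14 sensors, sampler
uniformity at 10^4 draws, nearest-cluster brute-force agreement over 1000
random queries, support-matrix property sweeps over 100 random
configurations, label recovery on 245 training / 105 held-out instances,
and the stability experiment at 50 repetitions for K ∈ {1, 30}.

## Known limitations

Segmentation is assumed done upstream; the package offers no change-point
or sliding-window machinery. The cluster-count upper bound is a heuristic
tied to the class count, not to the subset size or sample size, so empty
clusters still occur and are dropped. k-means runs once per classifier
with random initialisation — deliberately, as ensemble averaging is the
variance control — so individual collections can be poor. And the binary
encoding's advantage inverts by construction whenever two activities use
the same sensor set but differ in counts or order.
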