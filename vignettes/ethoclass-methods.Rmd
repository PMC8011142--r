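---
title: "Classifying animal behaviour from triaxial accelerometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying animal behaviour from triaxial accelerometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethoclass)
```

## The problem

Animal-borne accelerometers record acceleration along three body axes
(surge = longitudinal, sway = lateral, heave = vertical) at a fixed rate,
typically 3-25 Hz, in units of g. The signal mixes two components: a
*static* part, the projection of gravity onto the sensor, which encodes
body posture; and a *dynamic* part caused by movement. Because behaviours
combine characteristic postures with characteristic movement patterns,
summary statistics of short fixed-length signal segments ("bouts") carry
enough information for supervised classifiers to assign each bout a
behaviour category from an ethogram, given ground-truthed training data.

The practical motivation is *on-board* classification: if the tracker
itself classifies each bout and stores only a behaviour code, a 40-record
triaxial bout (120 values at 2 bytes) collapses to a single byte - a
240:1 compression - and a megabyte of flash holds weeks of continuous
behavioural data. `ethoclass` implements the full pipeline: segmentation,
feature calculation, classifier training and validation, and export of
trained models to compact parameter structures with dependency-free
inference engines written the way microcontroller firmware would run
them.

## Segmentation

`segment_series()` cuts a stream into consecutive, non-overlapping
windows of `bout_len_records` samples, starting at the first sample; a
trailing partial window is discarded rather than padded, since every
feature assumes a complete bout. A window is retained only if all its
samples carry the same behaviour label under the half-open rule
(`t_start <= t < t_end`); windows that span a label switch, or that touch
unlabelled time, are pruned and counted. Overlapping or sliding windows
are deliberately not offered: overlap would leak information between
cross-validation folds and inflate accuracy estimates.

Unlabelled time deserves a note: observation protocols rarely state how
gaps were encoded, so the reader treats any sample not covered by a label
interval as unlabelled, and segmentation prunes windows containing such
samples. For burst-mode loggers whose bursts are already one bout long,
each burst is simply one candidate window. For recordings whose original
bursts span several behaviours, the record count can be halved *before*
purity testing (halve first, then test), which is how the 96-record
roe-deer-style burst becomes two 48-record candidates.

## The feature catalogue

`compute_full_features()` returns 78 named statistics per bout, in seven
groups (30 + 12 + 13 + 2 + 6 + 6 + 9):

1. per axis: mean, variance, SD, coefficient of variation, skewness,
   excess kurtosis, maximum, minimum, range, Euclidean norm;
2. per axis pair: covariance, Pearson correlation, mean difference,
   SD of the difference;
3. from the static/dynamic decomposition: static and dynamic variance,
   mean and maximum absolute dynamic acceleration per axis, and ODBA;
4. pitch and roll (degrees);
5. per axis: mean absolute successive difference, variance of the signed
   successive differences;
6. per axis: main frequency (Hz) and its amplitude (g);
7. per axis: 25/50/75% quartiles.

Numerical conventions, chosen where more than one convention is in
common use and recorded here so results are reproducible:

* **Static component.** A centred running mean with configurable window
  (`acc_config(static_window=)`); the default window is the whole bout,
  i.e. static = per-axis bout mean. A full-bout window is the simplest
  reading of "gravitational component" for bouts short enough to hold one
  behaviour; a 2-s running mean can be configured where bouts are long.
  Note that with the full-bout default the static *variance* features are
  identically zero; they become informative only with shorter windows.
* **ODBA** is the mean over samples of the summed absolute dynamic
  acceleration, not the sum: the mean form is invariant to bout length,
  so values are comparable across datasets with different bout sizes.
* **Skewness and kurtosis** are the moment ratios m3/m2^(3/2) and
  m4/m2^2 - 3 (excess); variance and SD use the n-1 denominator;
  quartiles use linear interpolation (type 7). Zero-variance axes give
  0 for CV, skewness, kurtosis and correlation - never NaN - because
  resting behaviours genuinely produce constant bouts and classifiers
  must receive finite inputs.
* **Mean difference of successive points** uses absolute differences
  (the signed mean telescopes to ~0 and carries no information); the
  variance of successive differences uses signed differences.
* **Pitch** = atan2(mean_surge, sqrt(mean_sway^2 + mean_heave^2)),
  **roll** = atan2(mean_sway, mean_heave), both reported in degrees. The
  arctangent form is one of the two common conventions (the other uses
  arcsin of the normalised component); atan2 is defined for all non-zero
  mean vectors and behaves monotonically as the device rotates.
* **Main frequency**: DFT of the mean-removed signal (removing DC so a
  large posture offset cannot masquerade as a zero-frequency "main
  component"), maximum-amplitude non-DC bin up to Nyquist, ties broken
  toward the lowest frequency, amplitude scaled by 2/N so a unit
  sinusoid at an exact bin scores 1 g.

The simplified placement-specific sets mirror field practice: trackers
mounted in line with the spine or a limb (back, collar, leg) keep the
mean and SD of the surge and heave axes plus ODBA (5 features); ear tags
on ruminants keep the heave mean and SD, ODBA, and the heave main
frequency, which picks up jaw movement (4 features). Each simplified
value equals its full-catalogue counterpart, and is named after the
underlying file axis so the sub-vector identity holds by name.

## Classifiers, tuning, and validation

`etho_fit()` wraps six methods behind one interface: LDA (MASS), a
decision tree (rpart), an RBF-kernel SVM (e1071), a random forest
(randomForest), a single-hidden-layer softmax network (nnet, at most 500
iterations, no skip connections) and gradient-boosted trees (xgboost,
softmax objective, depth 6). Only the radial SVM kernel is offered - the
linear kernel is consistently inferior on this problem. Features are
standardised before SVM (via the backend, constant columns excluded) and
ANN (in-package, centre/SD stored in the model). LDA is fragile under
feature correlation, so `prune_correlated_features()` runs first at
cutoff 0.7: while any off-diagonal |r| exceeds the cutoff, the pair with
the largest |r| loses the member with the larger mean absolute
correlation against the remaining features. Constant columns correlate
with nothing and are never removed for constancy alone.

Ensemble sizes default to ntree = 800 and nrounds = 10 with the full
feature set, and to the deliberately shrunken ntree = 20 and nrounds = 5
with simplified sets - the model-size reduction that makes on-board
storage practical, at a cost of at most a few accuracy points.

`tune_classifier()` is an exhaustive grid search maximising mean
stratified-CV overall accuracy, with ties broken toward the simpler
model (fewer trees/units, smaller cost, stronger regularisation, larger
cp). SVM and ANN are the two methods that genuinely need tuning, and
they need *re*-tuning whenever the feature set changes; RF and XGBoost
perform well at defaults. `default_tuning_grid()` exposes the package's
grids: log-spaced over decades for the RBF parameters
(gamma in 10^(-3..-1), cost in 10^(0..2)), the standard shape for RBF
search spaces, since useful gamma values vary by orders of magnitude
with feature-space dimension.

`cross_validate()` performs stratified 10-fold validation: within each
class, shuffled indices are dealt so per-class fold sizes differ by at
most one, the remainder going to seeded-random folds. Each fold is used
for validation exactly once and never for training in that run. Per
fold it records the confusion matrix, overall accuracy (trace/total,
algebraically identical to the one-vs-rest (TP+TN)/total form) and
per-class F1 = 2RP/(R+P) with the 0/0 convention F1 = 0. Fold means are
reported with 95% confidence intervals using Student t with k-1 degrees
of freedom - slightly conservative at k = 10 compared with the normal
1.96 factor, and the defensible default when the fold count is small.

## Compact export and the on-board engines

`export_compact()` reduces a trained model to the minimal structure a
microcontroller needs:

* **SVM**: support vectors (in scaled feature space), dual coefficients,
  per-pair intercepts, per-class SV counts, per-feature centre/scale and
  gamma. Prediction evaluates the RBF kernel against every SV and holds
  a one-vs-one vote, which is why SVM is by far the slowest and largest
  on-board option - its footprint grows with the SV count.
* **ANN**: dense weight matrices and biases for the two layers plus the
  feature scaling; prediction is one matrix-vector product per layer,
  a logistic hidden layer and a softmax argmax.
* **RF / XGBoost**: per-tree node arrays of (feature index, threshold,
  left child, right child, leaf value); traversal uses comparisons only.
  Forest trees vote with their leaf class; boosted trees accumulate leaf
  scores per class and the largest summed margin wins - the softmax is
  omitted because it is monotone in the margins and cannot change the
  argmax (the margins stay inspectable for exactly that reason).

Two conventions make the engines exactly equivalent to their backends.
First, the traversal rule is fixed at *strictly less than* goes left;
randomForest splits on `<=`, so the exporter nudges each RF threshold up
to the next representable double, which is an exact translation between
the two rules. Second, every tie (SVM votes, forest votes, ANN/boost
argmax) resolves to the alphabetically first class label; backend tie
rules differ and are undocumented, so a single published rule makes the
residual disagreements auditable - engine/backend comparisons exclude
exactly the tie-flagged rows, which the engines report via the `ties`
attribute. The engines run on plain arrays with no reference to the
training backends, so they can be transcribed to embedded C verbatim.

`model_storage_bytes()` counts parameters at a configurable width
(default 4-byte values): ANN storage is governed by the weight count,
tree ensembles by the total node count (4 values per node), SVM by the
support-vector matrix. `compression_ratio()` and `storage_days()` do
the deployment arithmetic in exact integer/rational form: a 40-record
bout at 2 bytes per value compresses 240:1 against a 1-byte behaviour
code, and 2^20 bytes of memory hold floor(2^20 / (86400/3.8)) = 46 days
of codes at one 3.8-s bout per code.

## The synthetic generator

`generate_series()` and `generate_labelled_bouts()` emulate the
statistical structure the classifiers rely on - distinct postures and
dynamic movement traits - with the simplest model that has closed-form
feature expectations: per behaviour, a unit-norm gravity projection plus
a per-axis sinusoid with random phase plus white Gaussian noise, and
exponential (memoryless) dwell times between behaviour switches, with
the next behaviour drawn uniformly from the others. Closed forms used by
the tests: the bout mean approaches the posture, the main-frequency
feature equals the sinusoid frequency at exact bins, and ODBA approaches
(2/pi) * sum of amplitudes, since the mean of |sin| is 2/pi.

Three presets fix the study conditions: `"stork"` (back placement,
40-record bouts at 10.54 Hz, four bird-like behaviours), `"cow"` (ear
placement, 1500-record 1-min bouts at 25 Hz, behaviours separated by
heave-axis jaw frequency), and `"separated4"` (four behaviours with
distinct postures and amplitudes, 0.05 g noise, stork-like recording) -
the benchmark condition under which all four on-board methods should
recover behaviours at >= 0.90 cross-validated accuracy. Benchmarks in
the tests and the acceptance script use 200 bouts per class for
training-and-validation runs and 500 held-out bouts for engine/backend
comparisons; these sizes give stable accuracy estimates while keeping a
full run in tens of seconds.

What the generator does *not* emulate - and hence what passing these
benchmarks does not show about field data: inter- and intra-individual
variation (devices shifting on the animal, age/sex/mass differences),
non-stationary gait harmonics, behaviours defined as heterogeneous
"remainder" categories, and label noise from imperfect ground-truthing.
Real datasets separate far less cleanly; on them, expect the usual
ranking (SVM/RF/XGBoost strongest, ANN close behind, DT and LDA weaker)
rather than near-perfect recovery. Two synthetic behaviours sharing
posture and amplitude will show exactly the pairwise F1 degradation that
heterogeneous categories show in the field.

## Known limitations

* Fixed-length segmentation only; variable-time segmentation can improve
  accuracy for behaviours with irregular episode lengths but is out of
  scope.
* The LDA and DT models have no compact export: they were not candidates
  for the on-board role.
* Storage accounting reports parameter counts at a chosen width, not the
  exact flash layout of any particular firmware (alignment and padding
  are compiler-specific).
* The generator's closed-form structure is oracle-friendly by design;
  it is not a biomechanical gait model.
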