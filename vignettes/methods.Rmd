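---
title: "Methods: feature-based classification of resting-state fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-based classification of resting-state fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fnirsdx)
```

## The problem

Resting-state functional near-infrared spectroscopy (fNIRS) measures
concentration changes of oxygenated (HbO), deoxygenated (HbR) and total
(HbT = HbO + HbR) hemoglobin through the scalp. A diagnostic classifier for
a condition such as Parkinson's disease can be built on summary features of
these signals: each subject contributes 22 channels x 3 chromophore bands x
(6 temporal + 6 spectral) descriptors = 792 features, a logistic-regression
classifier is trained on a selected subset of them, and performance is
estimated by stratified k-fold cross-validation (k = 5 or 10).

With only 40 subjects against 792 features, feature selection is the crux.
The package implements a two-stage ensemble: three filter rankings (mean
absolute difference, mutual information gain, Fisher score) are combined by
a two-of-three vote over their top p % (p swept from 1 to 10, keeping the
most accurate voted subset), merged by union with the supports of an
elastic-net logistic model and an L1-penalized linear SVM, and the combined
candidate set is then reduced by a wrapper search — greedy forward/backward
selection or a genetic algorithm — whose fitness is cross-validated
classifier accuracy. A second experimental setting skips the ensemble and
searches the full 792-feature universe directly.

## The synthetic cohort generator

Because the original clinical recordings are an external download, the
package ships a generator that emulates their geometry and statistical
structure, and every test runs against it. A record is a sum of sinusoidal
physiological components with per-channel random phase and small frequency
jitter, plus white measurement noise:

| component   | centre (Hz) | HbO amplitude (uM) |
|-------------|------------:|-------------------:|
| cardiac     | 1.1         | 0.25               |
| respiratory | 0.25        | 0.15               |
| Mayer wave  | 0.10        | 0.40               |
| slow drift  | 0.012       | 0.20               |

HbR receives each component scaled by -0.3 (anti-correlated, as in cortical
physiology) with half the noise; HbT is constructed as the exact sum. The
Mayer wave is deliberately the largest component so that every channel has
a known dominant spectral peak, giving the spectral features a ground
truth. Two channels are "short-separation" channels carrying only the
superficial systemic components at half amplitude; they are kept in the
feature layout as ordinary channels, since the recording montage counts 22
signals, and an optional short-channel regression is out of scope.

The class difference is injected on a configurable channel subset (default
channels 1–5): for a case subject the Mayer-wave amplitude is scaled by
`1 + effect_size` and its centre frequency shifted by `0.01 * effect_size`
Hz. Both a temporal family (variance, zero-crossing statistics) and a
spectral family (energy, dominant frequency) are therefore discriminative,
which is what the recovery tests require. `effect_size = 0` makes the label
exactly independent of the data. The published study gives no amplitude or
noise statistics for its recordings, so these defaults are plausible
resting-state magnitudes (fractions of a micromolar), chosen once; with
`effect_size = 2` the cohort is nearly separable, matching the regime in
which the original pipeline reports perfect cross-validated metrics.

Randomness is handled by one root seed from which each subject derives a
private stream (`seed * 48271 + index * 65537 mod 2^31 - 1`, with case and
control index ranges disjoint), so enlarging a cohort never perturbs
existing subjects.

What the generator does *not* emulate: 1/f background spectra, spatial
correlation between neighbouring channels, task-evoked responses,
systemic transients, or realistic optode-scalp coupling variation. Passing
recovery and null tests on this generator demonstrates that the pipeline's
machinery is correct and calibrated, not that the clinical effect itself is
reproduced.

## Signal conditioning

**Optical conversion.** The modified Beer–Lambert operation solves the
2x2 extinction system per sample. Default coefficients are standard
order-of-magnitude values for a 757/843 nm LED pair expressed per uM and
cm, with DPF 6 and 3 cm separation; synthetic data are generated directly
as concentration changes, so this operation is exercised by a
forward-then-invert identity rather than being on the main path.

**Channel pruning.** The recording protocol only states that poor channels
were eliminated. The package scores each channel by the absolute
correlation of the cardiac-band (0.7–1.5 Hz) filtered HbO and HbR traces —
a scalp-coupling-index-style criterion: a well-coupled optode sees the same
cardiac pulsation in both chromophores. Threshold 0.7 by default. Pruned
channels stay in the layout with `retained = FALSE` and their features are
filled with the cohort column median, keeping the 792-column layout stable
across subjects.

**Motion correction** is deliberately simplified (the original cites an
external spline + wavelet method without defining it): samples deviating
from a ~1 s running median by more than `detection_zscore` robust standard
deviations are replaced by natural cubic-spline interpolation, then Haar
wavelet detail coefficients beyond the same robust z level are clipped. The
Haar pyramid handles arbitrary lengths by carrying the odd sample of a
level into the approximation. `detection_zscore = Inf` disables the
operation entirely. This corrects transient spikes and step shifts well on
synthetic fixtures (>= 80 % of injected spike samples flagged) but is not a
reimplementation of the cited algorithm.

**Standardization** is fitted on a designated row subset and applied with
the stored statistics, so the same transform extends to held-out rows.
Zero-variance columns pass through centred, with the sd treated as 1 and a
flag raised. The default pipeline standardizes on the full cohort before
selection, replicating the original protocol's order; see "Leakage" below.

## Feature conventions

The source material names the features without defining estimators; the
package fixes one documented convention per feature (switchable only by
code, emitted in the feature dictionary):

- Zero crossings are sign changes of the mean-removed trace; a sample
  exactly at zero counts once; crossings are linearly interpolated between
  samples. Resting concentration traces have arbitrary offsets, so mean
  removal is the defensible reading.
- "Time from a zero crossing to a peak" is the mean interval from each
  crossing to the next local extremum of the mean-removed trace.
- The spectrum is the one-sided magnitude of the DFT of the mean-removed,
  untapered signal, DC excluded, scaled so that the sum of squared
  magnitudes equals the time-domain energy (Parseval).
- Skewness and kurtosis are population moment ratios (kurtosis
  non-excess); variance divides by N. A constant trace returns variance 0
  and skewness 0 with a flag; a trace with fewer than two zero crossings
  returns the record duration as a flagged sentinel for features 5–6.

## Ranking and selection choices

- Top-p % set size is `ceiling(p * d / 100)` — non-empty at p = 1 (8 of
  792). Rank ties break by ascending feature index, for determinism.
- The MIG estimator discretizes each feature into `min(10, floor(n/4))`
  equal-frequency bins using average ranks (invariant to monotone
  transforms and row order) and computes plug-in mutual information in
  bits.
- Fisher scores weight class means by class size; 0/0 is 0 and a positive
  numerator over zero within-class variance is `Inf`, which sorts first.
- "Combining" the three selector subsets means set union: at n = 40 the
  intersection of heterogeneous selectors is typically near-empty, and the
  ensemble's stated purpose is to pool strengths.
- The elastic-net penalty is chosen by internal 5-fold CV at
  `lambda.1se` (the sparser model within one SE of the optimum — the
  stabler choice at n = 40), backing off along the path if that empties
  the model. The L1-SVM (squared hinge, FISTA) picks its penalty from a
  descending log grid by internal CV accuracy, preferring the sparsest
  non-empty model among ties. Both selectors are capped at n active
  coefficients: beyond that a penalized linear selection is
  unidentifiable, and uncapped runs occasionally return degenerate
  300-feature supports on null data.
- The vote-sweep evaluator and all search fitnesses use cross-validated
  (not training) accuracy; ties in the sweep prefer the smaller subset,
  then the smaller p.

## Search

The genetic algorithm follows the published configuration: population
1000, 100 generations, single-point crossover applied to 5 % of parent
pairs, 3 % per-bit mutation, accuracy fitness. The 0.05 crossover
probability is unusually low for a GA but is implemented as printed.
Unstated details are fixed as: size-2 tournament selection (the
"two winners" reading; roulette available), elitism 1 (which guarantees
the non-decreasing best-fitness trace the tests assert), initial bit
probability 0.5, and a mask-keyed fitness cache that changes cost, never
results. The empty mask has fitness 0 by convention. Greedy forward
(backward) wrapper search adds (removes) the best feature per step with
ties toward the lowest index and stops when no step strictly improves
(any removal strictly harms) fitness. An exhaustive oracle over up to 16
features grounds all searches in tests: greedy search provably matches it
on additively separable fitnesses, and the scaled-down GA (population
100, 20 generations) attains it on 10-feature planted problems.

## Evaluation

The logistic classifier is fitted by IRLS with step-halving and a tiny
ridge (1e-8) that only conditions the Newton system on separable subsets;
iteration stops early once the deviance is numerically zero, since a
separated fit cannot classify better. Folds are stratified (the balanced
20/20 design makes this the safe default) and shuffled under a stated
seed; aggregate accuracy/precision/recall/F1 are the means of the per-fold
metrics, matching the original protocol. AUC is reported both pooled over
all held-out probabilities (headline — per-fold AUC on 4-subject folds is
unstable) and as the per-fold mean. Metrics with zero denominators are
returned as flagged `NA`, never silently 0.

## Leakage

The default execution replicates the original order of operations:
standardization and feature selection are fitted once on the full cohort,
and cross-validation then evaluates the selected subset. With 792
candidate features and 40 subjects this optimistically biases the CV
estimate — selection has seen the held-out labels. The pipeline therefore
also offers `leakage_mode = "nested"`, which re-fits standardization and
the entire selection stage inside every training fold; only this mode
yields an unbiased estimate. The package's null-calibration checks
(cohorts with `effect_size = 0`) use the nested mode for exactly this
reason: under the default order, null accuracy lands far above chance by
construction, which is a property of the protocol, not of the generator —
the nested estimate is the one that must be centred at 0.5.

## Problem sizes used by the test suite

Unit tests run on 60-second, 4–22-channel cohorts of 4–10 subjects.
End-to-end checks use the full design — 40 subjects, 22 channels, 360 s at
25 Hz — with scaled-down search budgets chosen once: GA population 60 x 12
generations for effect-recovery runs and 100 x 20 for the 10-feature
oracle comparisons; the repeated null-calibration runs use the
forward-WFSS variant of setting A, whose nested re-selection is cheap and
deterministic. In all second-stage searches the candidate universes
(tens of features) are far smaller than the 792-feature start.
Conditioning (pruning, motion correction) is exercised by its own tests
and disabled in the multi-run end-to-end checks, whose synthetic inputs
are clean by construction.

## Known limitations

- The feature conventions (zero-crossing trace, spectral estimator,
  moment definitions) are one defensible reading of under-specified
  definitions; alternative readings would change feature values but not
  the pipeline structure.
- The motion correction is a simplified stand-in for the cited method.
- The generator's independence across channels makes channel-level
  recovery easier than on real data with shared systemic physiology.
- GA defaults (population 1000 x 100 generations) are computationally
  heavy with a CV-accuracy fitness; the scaled-down budgets used in tests
  are where the correctness evidence lives.
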