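---
title: "Detecting retropharyngeal edema from weakly annotated MRI stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting retropharyngeal edema from weakly annotated MRI stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Retropharyngeal edema (RPE) is a hyperintense band on axial T2-weighted
water-only (fat-suppressed) MRI, located between the superior pharyngeal
constrictor muscle and the prevertebral muscles. In acute neck infections it
is a prognostic imaging biomarker: patients showing RPE are at substantially
higher risk of a severe course of illness. Reading it requires an
experienced neuroradiologist, which motivates an automated detector that
works from *weak* annotations — a per-patient binary label plus only the
uppermost and lowermost slice indices showing the edema, rather than
pixel-wise lesion masks.

`rpedetect` implements a two-stage detector for this setting:

1. **Slice stage.** A lightweight convolutional classifier — the contracting
   path of a U-Net followed by a small dense head and a single sigmoid
   unit — scores every axial slice with a probability of showing RPE.
2. **Patient stage.** For each patient, the ordered slice scores are reduced
   to a single decision statistic: the maximum over all runs of five
   consecutive slices of the mean slice score (the *windowed-mean maximum*).
   A patient is called positive when this statistic reaches a threshold
   chosen to maximize Youden's index ($J = \text{sensitivity} +
   \text{specificity} - 1$) on the training set. Slice labels are then
   *finalized*: every slice of a predicted-negative patient is negative by
   fiat, and slices of predicted-positive patients are thresholded at a
   second, slice-level maximal-Youden threshold, also learned on training
   data only.

The patient stage exists because naive per-slice thresholding destroys
patient-level specificity: with 26–60 slices per patient, even a low
per-slice false-positive rate makes a false-positive *patient* almost
certain. Requiring five consecutive suspicious slices on average — while a
window of exactly five keeps sensitivity for edema visible in only 2–3
slices — suppresses isolated false positives without giving up thin lesions.

## Data model and conventions

- A patient is a `volume_stack`: an ordered 3-d array of square axial
  slices plus pixel pitch and slice spacing. Slice order is fixed at
  construction and nothing in the package permutes it.
- Weak annotations are tibbles with `patient_id`, `patient_label`, and the
  0-based, *both-ends-inclusive* `uppermost_idx`/`lowermost_idx` range.
  Inclusivity follows the annotation semantics (the annotated endpoints
  themselves show edema); 0-based indexing is the internal convention, and
  `read_annotations(index_base = 1)` accepts 1-based files.
- `expand_annotations()` turns the weak range into per-slice 0/1 labels:
  everything inside the range is positive, everything else (and every slice
  of a negative patient) negative.

## Slice standardization

Each slice is (in this order) resized to 128 × 128 with bilinear
interpolation, min–max normalized onto $[0, 1]$ with *per-slice* statistics
($x \mapsto (x - \min x)/(\max x - \min x)$), and rounded through IEEE
single precision (the storage format of the training pipeline). Normalizing
*after* resizing guarantees the endpoints 0 and 1 are attained exactly
despite interpolation; resize outputs are additionally clamped to the input
range. A constant slice normalizes to all zeros rather than erroring —
background-only slices must not crash a pipeline. Bilinear interpolation is
the conventional default for downsampling classifier inputs; the resize is
delegated to EBImage.

## Augmentation

Three augmentation schemes are supported, each doubling the training
partition by appending one transformed copy per slice (labels copied):

- `reflect_vertical` — left–right mirror across the anatomical midline; the
  default, since the neck is approximately left–right symmetric, making it
  the anatomically plausible augmentation;
- `rotate_90_cw` — a clockwise quarter turn;
- `blur_3x3` — a normalized 3 × 3 Gaussian
  ($[1,2,1]\otimes[1,2,1]/16$, replicated edges).

Augmentation applies to the training partition only; validation and test
slices never pass through it (and the leakage tests would catch it if they
did).

## The classifier and its training protocol

The network is `n_encoder_blocks` (default 4) repetitions of two 3 × 3
same-padded convolutions with ReLU followed by 2 × 2 max-pooling — the
U-Net contracting path — then a flatten, one dense layer of width 128, and
a single sigmoid unit. With a 128-pixel input and four blocks the spatial
size before the flatten is 8 × 8. Training minimizes binary cross-entropy
with Adam (learning rate $10^{-3}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
conventional defaults) for at most 15 epochs, stopping early once the
validation loss has failed to improve for 5 consecutive epochs and
restoring the weights of the best validation epoch — the standard reading
of "no improvement for five epochs". No pre-trained weights are used
anywhere.

Two engineering choices deserve a note:

- **The engine is written in the package** (C++ via Rcpp/RcppArmadillo,
  single-precision im2col + BLAS matrix products) because the package's
  design goal is a self-contained pipeline with bit-reproducible training:
  every random draw (He initialization, epoch shuffling) is governed by an
  explicit integer seed, and two runs with the same seeds produce identical
  parameters.
- **Default widths are small** (filters 2/4/8/16 per block, batch size 4).
  The architecture is deliberately lightweight — the point of an
  encoder-only classifier is to train on an ordinary CPU — and profiling on
  a single core showed the skinny convolution products are memory-bound, so
  narrow filter banks and cache-sized minibatches dominate the
  accuracy/wall-clock trade-off at desk scale. Every width, as well as the
  batch size, is exposed in `network_config()`/`training_config()`, so a
  wider bank (e.g. 32/64/128/256) is one argument away on faster hardware.

## Aggregation details

- Candidate thresholds for the Youden maximizer are the distinct observed
  training scores plus one sentinel above the maximum; this sweeps every
  achievable confusion matrix exactly (midpoints would give the same
  decisions). The decision rule is tie-inclusive (`score >= threshold`), so
  the maximizing candidate itself classifies positive.
- Among thresholds with equal maximal $J$, the *largest* is returned — the
  most specific operating point, matching the algorithm's purpose of
  suppressing false-positive patients. If no candidate attains $J > 0$
  (e.g. all scores identical), a warning is emitted and the sentinel wins.
- Score vectors shorter than the window are an error, not padded: real
  stacks have at least 26 slices, and padding would distort the means.
- The window length (5) is exposed as `window` but is part of the method's
  definition; the slice-level threshold is fitted on all training slices.

## Evaluation and statistics

Accuracy, sensitivity and specificity come from the finalized labels;
AUROC at the slice level from the raw slice scores, at the patient level
from the windowed-mean-maximum statistic. The AUROC estimator is the
rank-based Mann–Whitney probability with half credit for ties (delegated to
pROC, and cross-checked in the tests against an explicit pairwise count).
Undefined ratios (zero denominators, e.g. a single-class test fold) are
reported as missing with a warning, never as 0 or 1, so averages over
iterations are not silently inflated.

Paired comparisons between method variants use the two-sided Wilcoxon
signed-rank test over the 30 per-iteration values (zero differences
dropped; exact distribution where available, otherwise the
continuity-corrected normal approximation, as implemented by
`stats::wilcox.test` and cross-checked against exact sign-flip enumeration
in the tests). Because many comparisons are made, only $p < 0.01$ and
$p < 0.001$ are treated as significance tiers; star annotations
(\*, \*\*, \*\*\* at 0.05/0.01/0.001) are kept for report formatting.

The padded-vector baselines (`baseline_patient_classifier()`) right-pad
each patient's score vector with zeros to a common length and delegate to
`randomForest` or `e1071::svm` with a fixed seed; test scores are binarized
at the training-set maximal-Youden threshold, mirroring the main
algorithm's protocol. Two departures from pure library defaults were forced
by that protocol: the random-forest threshold is selected on out-of-bag
votes (refitting-set probabilities are essentially 0/1, which pushes the
Youden maximizer to a degenerate edge), and the SVM uses a linear kernel —
the padded score vector is a linear-margin representation, and a radial
kernel at cohort-scale sample sizes makes every training vector a margin
support vector with decision values pinned to ±1, leaving the training-set
threshold nowhere to generalize.

## Cross-validation protocol

`make_folds()` draws five near-equal patient-wise folds **once** and reuses
them across six repetitions (30 iterations): repetition-level randomness
comes from re-initializing the network and from drawing a fresh random 30%
of the training *patients* as the validation set in every iteration. The
validation draw is patient-wise — a slice-wise draw would leak patients
across the train/validation boundary. With 479 patients the fold sizes are
{95, 96, 96, 96, 96}, and each iteration uses 20% of patients for testing,
24% for validation and 56% for actual training. The classifier is rebuilt
from a fresh seed every iteration; no parameter state crosses folds.
`run_experiment()` writes per-iteration artifacts (metrics TSV, thresholds
JSON, test predictions TSV) and resumes from them, so a partial run can be
completed, and two stored runs can be compared with `compare_runs()`
without retraining.

## The synthetic phantom

Patient MRI from the motivating clinical setting is private, so the package
ships a phantom generator that emulates the *stated* geometry: 26–60 slices
per stack, square matrices of 256/384/512 pixels, pixel pitches
0.342–0.781 mm, slice spacings 4–6 mm, and a cohort prevalence of ~50%
positive patients. A phantom slice is air background outside a jittered
ellipse ("neck"), homogeneous tissue inside, and — on lesion slices — a
thin hyperintense crescent at a fixed fractional position anterior to the
ellipse centre, at 1.8 × tissue intensity by default, plus additive
Gaussian noise. A positive patient carries the crescent on a contiguous
slab of 2–10 slices (honouring that real RPE may span only 2–3 slices),
placed uniformly along the stack; the slab endpoints become the weak
annotation, so ground truth is consistent by construction.

What the phantom does **not** emulate: real anatomy and its confounders
(muscle edema, abscesses, vessels), Rician noise statistics, bias fields,
partial-volume effects, or inter-patient intensity variation beyond
geometry jitter. Additive Gaussian noise is used deliberately — at the
phantom's contrast the Gaussian/Rician distinction is immaterial for
pipeline testing and keeps the generator dependency-free. Consequently,
passing the synthetic-recovery checks demonstrates that the pipeline's
plumbing, training loop, aggregation and protocol are correct and
leak-free — not that the classifier would reach any particular accuracy on
clinical data. The null phantom (lesion ratio 1) paints nothing and is used
to verify the pipeline reports chance-level discrimination when there is no
signal.

Setting `lesion_intensity_ratio = 1` makes positive and negative slices
bit-identical; the generator is reproducible bit-exactly from its config
and seed.

## Numerical choices and degenerate inputs

- Normalization of a constant slice returns zeros (see above).
- Training with a single-class training set warns and proceeds; an empty
  training set errors.
- A zero learning rate leaves weights bit-identical (useful for exercising
  the early-stopping rule: a constant validation trace halts at epoch
  1 + patience).
- Equal validation losses count as "no improvement" (strict `<`), so a
  flat trace stops as early as possible.
- `windowed_mean_scores()` uses a cumulative-sum formulation; scores are
  probabilities in $[0,1]$, far from the regime where that loses precision.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use a 60-patient phantom cohort
at the full stated geometry: a single cross-validation iteration for the
high-contrast recovery check, and one full five-fold repetition for the
null phantom — pooling each patient's single held-out score gives the
chance-level AUROC an evaluation size of 60 patients, whereas a lone
12-patient fold would leave the sanity band far too often for purely
statistical reasons (its standard deviation under the null is about 0.16).
The null repetition trains without augmentation: a no-signal sanity check
does not involve the augmentation arm, and skipping it halves the training
cost of those five folds. Pipeline-invariant checks use 12-patient miniature
cohorts, and each oracle-equivalence suite draws 200–1,000 random
instances.
These sizes were chosen so the whole suite runs comfortably on one ordinary
CPU core while still exercising every stage at the study's geometry; the
protocol-arithmetic checks run at the full 479-patient scale since they
involve no training.

## Known limitations

- The phantom's simplicity means synthetic performance says nothing
  quantitative about clinical performance (by design; see above).
- The CNN engine is CPU-oriented and single-threaded; it is not intended
  for large-scale training, and the default widths trade capacity for
  tractability.
- Only the proposed encoder-classifier is built in; alternative slice
  scorers (e.g. an InceptionV3) can be compared by supplying their
  predictions to the aggregation/evaluation functions, which operate on
  plain prediction tibbles.
- DICOM ingestion is out of scope; volumes enter as NIfTI.
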