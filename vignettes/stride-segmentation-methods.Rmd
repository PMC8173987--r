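---
title: "Stride segmentation with a two-class hidden Markov model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stride segmentation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(strideseg)
```

## The problem

Foot-worn inertial measurement units (IMUs) record continuous 3-axis
acceleration and angular velocity while a person goes about their day. Most
gait-analysis pipelines start by cutting this stream into individual strides.
A stride here is delimited by two consecutive negative peaks of the
sagittal-plane angular velocity (the medial-lateral gyroscope axis, `gyr_ml`):
the dip just before the swing phase starts and the dip just after the stance
phase ends. Free-living recordings are much harder to segment than
laboratory walks: they mix steady gait with turns, shuffles, gait initiation
and termination, and the proportion of such non-steady strides grows as
walking bouts get shorter.

`strideseg` implements two segmenters over a shared signal-processing front
end, plus the evaluation framework to compare them and a synthetic generator
that makes the whole pipeline testable without any recorded data.

## Signal front end

All segmentation operates on `gyr_ml` only. The front end applies, in order:

1. **Body-frame transform** (`to_body_frame()`): one mounting rotation per
   sensor; the right foot's medial-lateral axes are sign-flipped after
   rotation so both feet share the same `gyr_ml` polarity and one model
   serves both sides. The mirroring convention is an inference — mounting
   matrices are deployment-specific — so the rotation is a caller-supplied
   argument, identity by default.
2. **Gravity alignment** (`align_gravity()`): the first 0.5 s window whose
   mean gyroscope norm stays below 5 deg/s is taken as a static frame, and
   the shortest-arc rotation maps its mean accelerometer vector onto
   (0, 0, +9.81) m/s². The 5 deg/s threshold and the 0.5 s window are
   package choices; the literature names static frames without quantifying
   them.
3. **Zero-phase low-pass** (`lowpass_zero_phase()`): a fourth-order
   Butterworth with 10 Hz cut-off applied forward and backward. The
   coefficients come from `signal::butter()`; the forward–backward pass is
   implemented in the package with odd-reflection padding and steady-state
   initial conditions because a naive double pass distorts the signal ends
   (we measured DC errors of order 1 on constant inputs without it). The
   result has exactly unit DC gain and no phase distortion, so filtering
   never moves a border minimum.
4. **Decimation by two** (`decimate_by_two()`): every second sample is kept,
   102.4 Hz becomes 51.2 Hz. The 10 Hz low-pass is the anti-aliasing filter
   (new Nyquist: 25.6 Hz). Annotations are never silently resampled;
   `reindex_annotations_by_two()` maps indices explicitly and moves any
   event by at most half a coarse sample.

Working at 51.2 Hz, the ±60 ms matching tolerance equals ±3 samples and the
200 ms snapping window spans ±5 samples.

## Features

`sliding_window_features()` computes, per sample, features over a centered
window (100, 220 or 500 ms; forced to an odd sample count so centering is
exact; clipped at the signal bounds rather than padded, because padding
would invent data exactly where bout transitions live):

* `raw` — the sample itself;
* `grad` — the least-squares slope over the window, per second;
* `var` — the population variance;
* `polyfit` — the three coefficients of a second-order fit on
  window-centered time, ordered (quadratic, linear, constant) so the
  constant coefficient is the smoothed signal value.

Features are z-scored per walking bout (`zscore_per_bout()`), which makes
the segmenter amplitude-invariant across bouts; columns with standard
deviation below 1e-12 are zeroed instead of dividing by noise.

## The two-class HMM

Strides are the labelled class; everything else inside a walking bout —
movement into and out of gait, within-bout rests — is the *transition*
class. Each class is a left-right HMM with diagonal Gaussian-mixture
emissions:

* **Stride model** (default 25 states): a strict chain `s_0 → … → s_n`
  with self-loops, pinned to start in the first and end in the last state.
  Each state corresponds to a sub-phase of the stride; time granularity is
  set by the state count.
* **Transition model** (default 5 states): the same chain plus a wrap edge
  from the last to the first state, with free start and end states, because
  non-gait movement has no fixed beginning, end or order.

Initialization divides every training sequence into `n` equal contiguous
segments and fits state `i`'s mixture to the pooled `i`-th segments
(k-means++ seeding with the operation's seed); all structurally allowed
transition edges start uniform. Baum-Welch then refines transitions, start
distribution (transition model only) and mixtures for at most ten
iterations — enough for these models in practice — with an additional
relative log-likelihood stopping tolerance of 1e-4. Structural zeros are
preserved exactly because expected edge counts inherit them. Probability
computations use scaled forward/backward passes with per-sample shifts
(equivalent to log-space evaluation); emission log-densities are floored at
−700 and variances at 1e-6.

The two trained models are flattened into one segmenter
(`combine_models()`): each training segment is decoded with its own class
model, the per-bout state sequences are merged (transition states first,
then stride states), and the full combined transition matrix is
re-estimated from the merged transition counts — this is where the
cross-class edges and the stride-to-stride wrap edge acquire their
probabilities, while emissions stay fixed. Because the sub-models pin
stride paths to enter at the first and leave at the last stride state, the
only cross edges that can be observed are the biomechanically meaningful
ones. Start/end distributions of the combined model come from the merged
sequences' first and last states with add-one smoothing; whether decoding
may start mid-stride is not dictated by the architecture, so the data
decide.

**Border prediction** (`predict_strides()`): Viterbi-decode a bout, mark a
border wherever the path crosses between classes or takes the
stride-last → stride-first wrap edge, and snap each border to the `gyr_ml`
minimum over the union of the two state-occupancy runs flanking that
change. Strides are the intervals between consecutive borders that bracket
stride-class stretches; the end of one stride may equal the start of the
next. Viterbi ties break toward the lowest state index so decoding is
deterministic.

Bouts are a *predefined input* at decode time, mirroring a protocol in
which bout detection precedes stride segmentation. Since a bout interval
spans first stride start to last stride end, the decoder works on a
*context window* — the bout expanded by 1.5 s on each side, clipped to the
recording and to the midpoint of the gap to the neighbouring bout — so the
transition states have signal to occupy at both ends. Features are z-scored
over the same window in training and prediction.

## The DTW baseline

The reference method is template matching by subsequence dynamic time
warping. All training strides are linearly resampled to their rounded mean
length and averaged (`build_template()`); amplitudes are divided by a fixed
500 deg/s scale so costs are comparable across recordings. Matching uses an
accumulated-cost matrix with free start positions, steps
{match, insertion, deletion} without slope weighting, and squared
difference as the local cost; matches are the local minima of the final row
below a maximum-cost threshold, with starts found by traceback and overlaps
resolved greedily by ascending cost (two adjacent strides legitimately
share a border sample, so only overlaps beyond a quarter of the shorter
match conflict). The threshold is tuned over the 2.0–5.0 grid in 0.25 steps
by pooled F1 on the training recordings; the exact cost normalization of
the historical implementation is not published, so the tuned value is not
transferable across implementations and the tuning step is part of the
method. Matched borders are snapped with the same 200 ms rule as manual
annotations.

## Evaluation framework

* `define_walking_bouts()`: both feet's strides merged on one timeline; a
  rest gap is the distance from one stride's end to the next stride's
  start; gaps above 2.5 s (boundary inclusive) split bouts; bouts need at
  least four strides, both feet combined.
* `match_strides()`: one-to-one matching; a stride counts as a true
  positive only if *both* borders fall within ±3 samples of a reference
  stride's borders. The assignment is a greedy sweep in start order; an
  exhaustive maximum-matching oracle in the test suite confirms the greedy
  result on hundreds of random instances (with a ±3-sample window and
  ~1 s strides, ambiguous multi-matches essentially cannot occur).
* `compute_metrics()`: precision, recall, F1; zero denominators yield 0
  with a degenerate flag rather than NaN, so pooled tables stay numeric.
  Counts are pooled (micro-averaged) before ratios are computed.
* `group_metrics_by_bout_length()`: bouts grouped by combined stride count
  (4–15, 15–30, 30–50, 50–100, 100–200, >200).
* `make_subject_folds()` / `grid_search()`: subject-wise cross-validation
  (no subject in both train and test of a fold) over the hyperparameter
  grid (window 100/220/500 ms; {raw}, {raw, grad}, {raw, var, polyfit};
  1/3/5/8 mixture components; 5–25 stride states; 3–12 transition states —
  720 configurations). Configurations that cannot train are recorded as
  failed and excluded from ranking instead of aborting the search.

## The synthetic generator

Real annotated free-living data cannot ship with a package, so
`generate_dataset()` produces labelled recordings whose statistical
structure carries exactly the features the method relies on:

* each stride is a smooth waveform with sharp negative border notches
  (depth 400 deg/s by default, reaching full depth only at the border
  sample so borders are unambiguous minima), a positive mid-swing peak
  (300 deg/s) and a near-zero stance plateau;
* per-foot strides are contiguous within a bout (consecutive strides share
  their border sample) and the right foot runs half a stride out of phase,
  so the merged-timeline bout definition applies;
* bouts are flanked by irregular low-frequency "transition" movement with
  heterogeneous per-flourish amplitude (log-normal, capped at 2.2× the
  100 deg/s scale) and occasional aborted partial steps — a swing-like bump
  beside a single shallow dip — emulating gait initiation and termination;
* bouts are separated by 4–8 s rest gaps; sensor noise is additive Gaussian
  (5 deg/s default); per-subject log-normal amplitude and duration
  multipliers (10%) provide inter-subject variability;
* with `short_bout_heterogeneity = TRUE`, strides in bouts shorter than 30
  strides are drawn from a library of stride types (steady, turning,
  shuffling, irregular) that vary the swing peak's height, position and
  multiplicity and attenuate the borders. This reproduces the documented
  failure mechanism of template matching — a single averaged template
  cannot cover diverse stride shapes, so atypical strides exceed the
  warping-cost threshold — while mixture-emission HMM states absorb the
  same diversity.

All randomness flows through one seeded stream (`rng_stream()`); identical
configurations reproduce datasets bitwise, and nothing touches the global
RNG state.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: biomechanical coupling between axes, soft-tissue
and mounting artefacts, freezing of gait, sensor drift and saturation, and
annotator disagreement about border placement. Synthetic borders are exact
by construction, so absolute synthetic scores overstate what any method
achieves on clinical recordings; only the relative structure (method
ordering, bout-length dependence) is meant to transfer.

## Problem sizes and run times

The shipped experiments are sized for a single CPU: the held-out recovery
experiment uses 8 subjects with one bout in each bout-length group
(6/20/40/75/150/210 strides, ~500 strides per subject), a 5/3
train/test split, and the compact operating point (10 stride states, 3
transition states, 1 mixture component, raw+gradient features, 220 ms
window). The bout-length experiment uses 6 subjects with a free-living-like
bout mix (many short bouts plus three long ones) and a mid-sized operating
point (15/5/3) — a reduced version of the full 25/5/8 configuration, which
trains identically but several times slower without changing the
qualitative outcome. Both experiments run end to end in a few minutes;
`scripts/acceptance.R` re-runs them from scratch.

## Known limitations

* Bout definition at decode time comes from the ground-truth annotations
  (the predefined-bout assumption); pairing the segmenter with an automatic
  gait-sequence detector is out of scope.
* The combined model's decoding may enter the stride chain on movement that
  merely resembles gait; downstream event detection is the natural
  false-positive filter and is not part of this package.
* Greedy stride matching is provably optimal only when no reference is
  compatible with two predictions that are both compatible with another
  reference; the test suite checks the realistic regime, not adversarial
  constructions.
* The DTW cost threshold is implementation-specific; published threshold
  values for other implementations should not be copied into `max_cost`.
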