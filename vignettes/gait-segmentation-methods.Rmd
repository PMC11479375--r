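---
title: "Ear-worn accelerometer gait segmentation: models, simulator and evaluation"
author: "mear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ear-worn accelerometer gait segmentation: models, simulator and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A single accelerometer worn at the ear records 100 Hz triaxial
acceleration (medio-lateral, anterior-posterior, inferior-superior axes,
units of g, range ±16 g) while a person walks. From that signal alone,
`mear` recovers the spatiotemporal structure of gait:

* the **temporal stepping sequence** — the initial contact (IC, heel
  strike) and final contact (FC, toe off) of each foot;
* **spatial stride characteristics** — stride length and stride width,
  regressed per gait cycle;
* **bout-level analytics** — mean, stride-to-stride variability
  (CV = 100·sd/mean, sample sd with ddof = 1) and left-right asymmetry
  (100·(1 − mean(smaller foot)/mean(larger foot))) of stride time, swing
  time, double support time, stride length and stride width.

The head is a favorable mounting site (it is mechanically stabilized
during gait and already hosts hearing aids and vital-sign sensors), but
it is far from the feet, so foot-contact timing must be inferred from
attenuated, orientation-dependent signatures. That motivates a learned
detector rather than hand-tuned peak picking.

# Models

## Temporal event network

A temporal convolutional network maps a standardized 3×200-sample window
(2 s) to two per-sample logit traces (IC and FC). Each of the 5 blocks is
a dilated 1D convolution (kernel 3, 32 channels, dilation 2^(i−1),
"same" padding so length is preserved) followed by batch normalization,
ReLU and dropout (0.2); a position-wise 1×1 convolution projects to the
2 output channels. The receptive field is
`1 + (kernel−1)·Σ growth^i = 63` samples (0.63 s), at least half a gait
cycle at every tested speed. Training minimizes binary cross-entropy with
logits against smeared labels; a sigmoid is applied only at inference.

**Label encoding.** Event targets are Gaussian bumps (peak exactly 1 at
the event sample, σ = 5 samples, truncated at 4σ, overlaps combined by
pointwise maximum). Smeared labels keep the loss informative for sparse
events; σ is configurable.

**Inference.** Recordings are scored in 50%-overlapping windows
(hop 100); overlapping sigmoid probabilities are averaged per sample,
which suppresses window-edge artifacts. Discrete events are local maxima
above a 0.5 threshold with a 0.30 s refractory period per channel
(the shortest plausible fast-walking step is ≈0.35 s); within a
refractory span only the highest peak survives. Both knobs are exposed
and documented; results in this package always use the defaults.

**Foot sides.** The network is side-agnostic (2 output channels). ICs are
assigned alternately left/right; the anchor convention assigns the first
IC to the sensor-ipsilateral foot. FCs alternate likewise, anchored by
the first FC, which is sided contralateral to its nearest preceding IC
(normal gait phasing: a foot's FC falls between the contralateral IC and
the next ipsilateral IC); alternation also sides the trailing FCs that
have no later IC context. Side-agnostic
summaries (means, CVs) are invariant under the anchor choice; asymmetry
is invariant under a global left/right swap by construction, so the
anchor ambiguity does not affect bout summaries. A 4-channel per-foot
variant would remove the ambiguity and is a possible extension. Probable
missed steps (an IC gap exceeding 1.8× the median IC interval) are
recorded as gap intervals; strides spanning them are flagged invalid
rather than silently dropped.

## Spatial stride regressors

Two independent networks regress stride length and stride width (cm)
from the acceleration spanning one gait cycle (ipsilateral IC to next
ipsilateral IC), standardized and linearly resampled to a fixed 200
samples. Each residual block applies two causal dilated convolutions
(padding followed by *chomping* of the overhang, so no activation
depends on future samples), each with ReLU and dropout; an additive
bypass (1×1 convolution when channel counts differ) carries the input
past the block. Temporal average pooling and a linear layer produce one
scalar. The pooled representation is the exact temporal mean of the last
block's activations; note that mean pooling is *not* invariant to
appending activation frames unless they equal the sequence mean — the
relevant guarantees are that pooling is exact and that constant
sequences of any length pool identically.

Design choices the underlying description leaves open, resolved here:

* **Fixed input length** via linear resampling to 200 samples (reusing
  the temporal window convention). The original duration can be appended
  as an auxiliary scalar input (`use_duration`), off by default.
* **One shared model for both feet**, with the foot side as a binary
  auxiliary input to the linear head, rather than side-specific models.
* **Plausibility gate**: cycles shorter than 0.5 s or longer than 4 s
  are outside the human walking range and are discarded (and counted)
  before resampling.
* **Target standardization**: regression targets are z-scored on the
  training subjects and de-standardized at prediction; this conditions
  the MSE loss.
* **Default architecture**: 3 residual blocks × 16 channels. Global
  average pooling aggregates evidence over the whole cycle, so a modest
  receptive field suffices for the amplitude- and shape-reading task;
  the small network also keeps single-CPU training practical.

## Training protocol

Subjects — never bouts — are split 80/20 into training and test sets, and
the training subjects into k = 5 cross-validation folds; no individual
appears in two partitions (the leakage hazard in repeated-measures
designs). Stratification uses each subject's speed-condition bout
counts, the only structured covariate the manifest carries. A grid
search over batch size, learning rate and epochs is provided
(`grid_search()`, default grid {32, 64, 128} × {1e-4, 1e-3, 1e-2} ×
{30, 50, 100}); the recovery experiment below fixes one configuration
instead of searching, to stay within a single-CPU budget. Within each
run, the epoch with the lowest validation loss supplies the returned
weights (an early-stopping flavor of model selection). Input
standardization is a robust scaler (median removed, interquartile range
divided out, per channel) fitted once on the pooled training recordings
and frozen — quartiles use linear interpolation between order statistics
(the common type-7 rule), and fitting on the training split only
prevents leakage.

**Orientation augmentation.** Sensor orientation varies between ears and
wearers, and a detector must not depend on it. During training, each
batch element is rotated by an independent random 3D rotation (per-axis
angles ~ N(0, 10°)) applied in raw acceleration space and folded into an
affine map on the standardized channels. Without it, both networks fit their training
subjects but fail on held-out subjects with unseen orientations; with
it, held-out performance approaches within-subject performance. This is
a training-data transform only — the simulator's orientation
distribution is untouched.

# The synthetic cohort simulator

Real recordings of this kind are not openly available, so the package
ships a simulator that emulates the walkway protocol: subjects cross a
6.7 m pressure-sensitive mat repeatedly at slow, preferred and fast
instructed speeds (6/8/10 walks by default) while wearing the ear
sensor.

**Footfall geometry first.** Both feet share the common gait-cycle
durations — on a straight walk, stride time is the sum of the two step
times and cannot differ between feet in steady state — so temporal
asymmetry is realized as the left-right *step-time split* (a phase
offset of the second foot inside each cycle), which keeps the feet
phase-locked instead of letting independent chains drift apart.
 Per subject and speed, cadence and stride
length are drawn around healthy-adult norms (cadence 95/112/125
steps/min ± 6 between subjects; stride length 110/128/145 cm ± 8;
stride-to-stride CVs ≈ 2.5%; temporal asymmetry ≈ 1%, spatial ≈ 1.5%;
stride width 8 ± 1.5 cm with ≈ 20% CV; stance fraction 62/60/58% of the
cycle, reflecting the shortening of double support with speed). Each
foot's IC chain accumulates independently drawn stride times; FCs sit at
the stance fraction of each cycle; heel x-positions accumulate drawn
stride lengths, and y-positions place the feet ± half a stride width
around the line of progression. The larger foot carries the configured
mean and the smaller `mean·(1 − asym/100)`, so the asymmetry formula
recovers the configured value exactly. Ground-truth stride records are
derived from the emitted events with the *same* machinery the analysis
side uses (`strides_from_events()`), plus the drawn lengths and the
perpendicular-distance width definition — generator and metrics
therefore agree to machine precision by construction, which is what the
self-consistency checks assert.

**Then the signal.** Ear acceleration is synthesized on top of the
events: gravity; a vertical harmonic at step frequency (plus a second
harmonic) whose local amplitude tracks the local stride length (ratio to
a 130 cm reference, 0.35 g at reference); an anterior-posterior harmonic
at step frequency and a medio-lateral harmonic at stride frequency; a
damped 13 Hz oscillation (τ = 50 ms, ≈0.8 g scaled by cadence) at every
IC; a smaller 8 Hz transient (35% of the IC amplitude) at every FC; a
per-subject 3D sensor-orientation rotation (per-axis angles ~ N(0, 8°));
and white Gaussian sensor noise (0.03 g). All randomness derives from a
master seed through counter-derived substreams, so cohorts reproduce
exactly, including under parallel generation.

**What the simulator does and does not show.** It produces learnable,
biomechanically plausible event signatures and a stride-length-encoding
amplitude, but it is not a musculoskeletal simulation: no turning,
stopping, stairs, non-gait activity, soft-tissue artifacts, or
pathological gait. Passing the recovery experiment demonstrates that the
pipeline's machinery — windowing, training, inference, event extraction,
cycle segmentation, regression and the agreement statistics — is correct
and that the networks can learn such signatures; it does not certify
accuracy on real ear-worn recordings. Stride width is deliberately *not*
strongly encoded in the signal (lateral head motion carries little
information about foot placement width), so the width regressor is
expected to fail on held-out subjects — mirroring the negative finding
for lateral gait characteristics with body-worn sensors generally.

# Evaluation machinery

* **Event matching**: predicted and annotated events pair greedily by
  ascending |Δt| among all pairs with |Δt| < 250 ms (strict), each event
  used once; remaining annotated events are FNs, remaining predictions
  FPs. On gait-like instances (inter-event spacing well above the
  prediction jitter) this greedy rule attains the brute-force maximum
  matching, which the test suite verifies on 1000 random instances;
  adversarial point configurations where greedy is suboptimal exist but
  cannot arise from refractory-limited detections. Time errors are
  reported as `t_annotated − t_predicted` (a late prediction is
  negative).
* **Detection scores**: recall, precision, F1 per event class, plus a
  support-weighted aggregate. Undefined ratios (zero denominators) are
  flagged `NA`, never silently zero; TP = 0 with both error kinds
  present gives 0 by convention.
* **Agreement**: RMSE (absolute, and relative to the mean of the
  ground-truth values of the comparison group), Pearson's r with a
  two-sided significance flag at α = 0.05, and the single-rater two-way
  intraclass correlation computed from the paired-measurement ANOVA mean
  squares. The common "ICC(3,1), absolute agreement" phrasing mixes
  McGraw-Wong conventions, so both variants are always computed:
  *consistency* ignores a systematic offset between methods, *absolute
  agreement* (the default) penalizes it. Interpretation bands: poor
  (<0.5), moderate (0.5-0.75), good (0.75-0.9), excellent (>0.9).
* **Speed dependence**: relative RMSE per subject × speed, compared
  across slow/preferred/fast with a one-way repeated-measures ANOVA
  (`F = MS_condition/MS_error`, df = (2, 2(n−1))); incomplete subjects
  are excluded with a warning. Both the ICC and the ANOVA are
  cross-checked in the tests against independent `aov()`-based mean
  squares to 1e-10.

# The recovery experiment and problem sizes

`run_pipeline()` is the package's end-to-end parameter-recovery
experiment: simulate a cohort of 12 subjects (3 walks per speed), split
80/20 by subject, train the temporal network (50 epochs, Adam, learning
rate 2e-3, batch 32, hop-100 windows, 10° rotation augmentation) and the
spatial regressors (60 epochs, learning rate 1e-2, batch 64), then
measure on the held-out subjects: per-class detection at 250 ms
tolerance and stride-length/width agreement on subject × speed mean
cells. The stride-length predictor is a small ensemble (two training
runs with different initialization seeds, predictions averaged), which
damps run-to-run calibration error of the amplitude read-out; the width
regressor uses a single run since it is reported, not gated. The cohort
size and epoch counts are the package's chosen problem sizes: large
enough that held-out IC F1 ≳ 0.95, FC F1 ≳ 0.85 and stride-length
relative RMSE ≲ 10% are reproducibly attainable, small enough to train
on one CPU in minutes. Stride width is reported but not gated, for the
reason above.

# Numerical choices and degenerate inputs

* Quantiles: type 7 (linear interpolation); IQR = 0 on any channel is a
  degenerate-data error, not a silent division by zero.
* CV uses the sample standard deviation (ddof = 1), unbiased at the
  small per-bout stride counts; configurable in principle via the stride
  table itself.
* Asymmetry with both per-foot means zero is 0; with exactly one zero it
  is undefined and flagged.
* Cycle resampling is linear interpolation with exact endpoints; a cycle
  of exactly 200 samples passes through unchanged.
* The networks' backward passes are hand-written and verified against
  central finite differences (<1e-5 relative error) in the test suite;
  batch normalization uses batch statistics during training and running
  statistics (momentum 0.1) at inference, so evaluation-mode forward
  passes are deterministic.
* Event extraction breaks peak-height ties toward the earlier sample;
  matching breaks |Δt| ties toward the earlier annotated, then earlier
  predicted event — all orderings are total, so results are
  reproducible.
* All training is seeded end-to-end (weight initialization, shuffling,
  dropout, augmentation); the full pipeline run twice with one master
  seed writes byte-identical metric files.

# Known limitations

* The simulator's harmonic-plus-transient signal model is a contract for
  testing the pipeline, not a claim of biomechanical fidelity; absolute
  accuracies on real recordings cannot be inferred from it.
* The 2-channel temporal network leaves a global left/right ambiguity
  resolved only by the anchor convention; sided statistics may be
  globally swapped on a single bout.
* Appendix-level architecture/hyperparameter details of the original
  networks are not public; defaults here are declared choices, exposed
  in `temporal_config()`, `spatial_config()` and the training functions.
* Stride-width regression is structurally weak from a head-worn sensor;
  its outputs should be treated as exploratory.
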