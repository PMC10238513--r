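---
title: "Attention-based patient-level classification of lung auscultation audio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based patient-level classification of lung auscultation audio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(auscultnet)
```

## The problem

Pediatric lung auscultation is recorded digitally at up to eight thoracic
sites per patient (one per quadrant, anterior and posterior), at 4 kHz and 16
bits. The goal is a patient-level diagnostic prediction over four categories —
control, pneumonia, wheezing disorder, bronchiolitis — together with an
interpretable account of *where in the respiratory cycle* the model listens.
`auscultnet` implements the full pipeline: a log-mel front end, a
convolutional classifier with temporal attention pooling, logistic
aggregation of the eight per-site scores, one-vs-rest binary models fused by
multinomial logistic regression, nested cross-validation with ensemble
external validation, a clinical age/respiratory-rate baseline, and the
Mean-Attention Difference (MAD) statistic aligning attention with annotated
respiration phases. Because clinical auscultation audio is rarely shareable,
the package also ships a synthetic breath-sound simulator so every stage can
be exercised and tested end to end.

## Front end

Recordings are converted to log-mel spectrograms with a 256-sample Hann
window (64 ms at 4 kHz) and a 64-sample hop (16 ms), i.e. 62.5 frames per
second. Magnitude spectra between 250 and 750 Hz are projected onto 32
triangular mel bands (HTK mel scale, endpoints exactly at the band edges) and
log-transformed. A 5-second clip yields a 32 × 313 matrix; frames are centred
with reflect padding so the frame count is `floor(len/hop) + 1`. Numerical
choices: a `log_floor` of `1e-10` is added before the logarithm; an explicit
time-domain band-pass filter is available but off by default, since the mel
projection already band-limits the representation.

Each mel band is normalized independently (spectrograms have no vertical
translation invariance), implemented as the model's input batch-norm layer
and, offline, by `fit_band_stats()`/`apply_band_norm()`. During training,
fixed-size inputs are made by random 5-second crops (zero-padding shorter
clips) — long enough for at least one full pediatric respiration cycle — and
SpecAugment masks 2 frequency bands (width ≤ 8) and 2 time ranges (width ≤
32 frames), filling masked cells with the band mean (the band-normalized
zero). Mask counts and widths are conventional values scaled to the 32 × 313
input; they are not critical and are exposed as arguments.

## Segment model and attention pooling

The classifier is a 5-block CNN (two 3 × 3 convolutions per block, batch
norm + ReLU, 2 × 2 average pooling and dropout 0.2 after the first four
blocks) with channel progression 64–128–256–512–1024; only the final width is
architecturally pinned, and the doubling progression is the standard way to
reach it. After the last block the frequency axis is averaged out, the time
axis is smoothed by summed max- and average-pooling (size 3, stride 1), and a
1024-wide fully connected layer produces one feature vector per *segment*
(one per 16 input frames; `T = ceiling(frames/16)`, so a 5-s clip has 20
segments). Two per-segment heads follow: a sigmoid prediction head `p(x_i)`
and a tanh attention head `v(x_i)`, normalized over segments,

$$g(x_i) = \frac{\exp v(x_i)}{\sum_j \exp v(x_j)}, \qquad
  p(x) = \sum_i g(x_i)\, p(x_i),$$

so the clip score is a convex combination of segment scores. At inference the
model consumes the entire recording, whatever its length (clips shorter than
one segment stride are zero-padded to the minimum).

**Receptive field.** The published mapping of segments to time uses a
78-frame receptive field (1296 ms; segments stride 256 ms). Tracing the
implemented architecture (10 convolutions, 4 ceil-mode poolings, size-3 time
smoothing) gives 172 frames, and `measure_receptive_field()` — which
backpropagates one interior segment's output to the input in inference
mode — confirms 172 empirically. The package keeps 78 frames as the default
time-mapping geometry of the standard model so that attention curves and MAD
use the published span convention, and reports the measured width alongside;
`model_config(rf_frames = NA)` switches the mapping to the traced width.

## Patient-level aggregation and fusion

Per-patient, the eight clip scores are ordered by the fixed site convention
(anterior right/left superior, anterior right/left inferior, then the
posterior quadrants) into a length-8 vector; patients missing any site are
excluded from aggregation. A logistic regression on these vectors gives the
patient probability. It is fitted on the pooled train + tune folds (the
aggregator itself needs no tuning set) with a fixed L2 penalty (strength 1 in
the convention `-(1/n)\,\ell + \mathrm{reg}/(2n)\,\lVert w\rVert^2`, solved
deterministically by glmnet at tolerance 1e-12). For the four-class decision,
the four binary models' site vectors are stacked into a 4 × 8 array, each
column is L1-normalized (a recording claimed by several models should count
less), zero-sum columns are left at zero rather than fabricating uniform
evidence, and the array is flattened class-major into 32 features for a
multinomial logistic regression.

## Training

Each binary model minimizes binary cross-entropy on clip-level predictions;
the clip label is the patient's diagnosis broadcast to all of its recordings
(the only consistent reading when no per-clip labels exist). Optimization
uses AdamW (weight decay 0.005) with a 1cycle schedule peaking at 0.001
(initial = max/25, final = initial/10⁴, cosine phases, 30% rise). Batches of
64 are drawn by balanced sampling: positives and negatives equiprobable, the
negative mass split equally over the three other diagnoses, and centres
equiprobable within each class — this guards against the documented hazard of
CNNs learning centre-specific background noise. One epoch draws exactly N
recordings (N = dataset size), in `ceiling(N/64)` batches. Training runs 100
epochs; from epoch 60 the tune fold is scored every epoch and the checkpoint
with the best *mean positional AUROC* (one AUROC per site, unweighted mean;
single-class sites dropped with a warning) is kept. All randomness is derived
from one seed, so runs are exactly reproducible.

## Evaluation

Nested stratified 5-fold cross-validation assigns each patient (with all of
their recordings) to one fold, preserving class proportions; every ordered
(test, tune) pair of folds forms one split, 20 in all. External-style
validation averages the per-split models' probabilities into a single
ensemble prediction per patient. Sensitivity and specificity are taken at a
fixed 0.5 threshold on the aggregator probability (the trade-off could be
tuned a priori; the package deliberately does not), with exact
Clopper–Pearson 95% intervals; AUROC is the rank statistic (ties half-credit)
with DeLong intervals truncated to [0, 1] — under perfect separation the
DeLong variance is zero and the degenerate interval is returned with a
warning. The clinical baseline is a logistic regression on age and
respiratory rate (standardized), grid-searched over strength
{0.01, 0.1, 1, 10, 100} × penalty {L1, L2} by mean tune AUROC on the same
fold plan, then refitted per split on train + tune; patients without a
recorded respiratory rate are excluded. The inference sweep crops recordings
from the start to 2.5–30 s in 2.5-s steps and scores position subsets of
size 8, 4, 2, 1 anchored on the anterior-superior sites (least heart/stomach
interference); reduced subsets get a re-fitted aggregator of matching width,
and the 30-s/8-position cell reproduces the standard pipeline exactly.

## MAD: aligning attention with respiration phases

For a recording with doctor-annotated inspiration/expiration intervals, each
segment is assigned to the phase overlapping the majority of its
receptive-field span (exact ties and segments with no annotated overlap are
left out). With \(\alpha_{in}, \alpha_{out}\) the mean attention over the
inspiration and expiration segments,

$$\mathrm{MAD} = \frac{\alpha_{out} - \alpha_{in}}
                      {\max(\alpha_{out}, \alpha_{in})} \in [-1, 1],$$

positive when the model attends to expiration. MAD is scale-free in `g`,
antisymmetric under swapping the phase labels, and undefined when a phase has
no segments (an error, by design). Since softmax attention is strictly
positive, \(\alpha_{in} = \alpha_{out} = 0\) cannot occur and needs no
special case. Cohort summaries report the per-diagnosis median and the
adjusted Fisher–Pearson sample skewness (`NA` below 3 recordings). Overlay
exports pair the spectrogram, attention curve and the phase intervals
selected by the MAD sign (inspiration if negative, expiration if positive).
Which binary model supplies the attention is a parameter: the
healthy-vs-pathological model is the conventional choice, but per-disease
models can be inspected the same way.

## The synthetic cohort: what it does and does not emulate

The simulator generates the statistical structure the pipeline assumes, not
thoracic acoustics. Breath sounds are Gaussian noise band-passed to
250–600 Hz, amplitude-modulated by the respiratory cycle (inspiration
duration ~ U(0.5, 1.0) s, expiration ~ U(0.8, 1.5) s, 50-ms ramps).
Inspiration is kept slightly louder (RMS 0.18 vs 0.17), per auscultation
convention, while leaving the control expiration/inspiration band-power
contrast within ±1 dB of zero so that phase preference in a control cohort
is genuinely uninformative. Class signatures: wheezing disorder plants a
frequency-modulated expiratory tone (f₀ ~ U(350, 650) Hz, ±20 Hz vibrato to
avoid a single-bin artifact, amplitude 0.30 chosen so the planted expiratory
band-power excess is ≥ 3 dB); pneumonia plants inspiratory crackles
(exponentially damped noise bursts of 5–20 ms) on a contiguous "lobar"
subset of 2–3 sites; bronchiolitis gets a mild diffuse wheeze plus crackles
on all sites. Each of two centres adds a distinct noise floor (hum at a
centre-specific frequency plus low-passed rumble and white noise) so that
centre-confound hazards can be reproduced. Ages and respiratory rates are
drawn class-conditionally (bronchiolitis youngest; elevated rates in all
disease classes; 5% of respiratory rates missing). Every planted event is
logged with its site, time and phase, and `planted_signal_check()` verifies
the log against the annotations.

Passing tests on this cohort demonstrates that the implementation recovers
planted, well-separated structure; it does not demonstrate clinical
performance. Real auscultation has heart and stomach sounds, device transfer
functions, inter-annotator disagreement, and far weaker class signatures —
none of which are modeled. Cycle durations are drawn independently of the
drawn respiratory rate covariate; the covariate feeds only the clinical
baseline.

## Problem sizes and numerical choices

The reference study conditions for end-to-end checks are the simulator
defaults: 120 patients (15 per diagnosis per centre, two centres), eight
30-second 4 kHz recordings each, cohort seed 1234. The package's
parameter-recovery runs (test suite and `scripts/acceptance.R`) use a reduced
model — 2 blocks with 4 and 8 channels, 10 epochs, tune selection from
epoch 6 — on one nested-CV split; this desk-scale configuration trains in a
few minutes on one CPU while leaving the task solvable by construction (a
trivial expiration/inspiration energy-ratio classifier already separates
wheeze from control with AUROC > 0.9, so a failing CNN indicates a pipeline
bug, not impossible data). Other fixed numerics: batch-norm ε = 1e-5 and
momentum 0.1 with unbiased running variance; ceil-mode 2 × 2 average pooling
averaging only real cells; time smoothing divides the average by 3
(zero-padded) while the max ignores padding, matching the usual
implementation; time-pool argmax ties break to the earliest frame; BCE inputs
clamp to [1e-7, 1 − 1e-7]; glmnet fits use a short descending lambda path
ending at the requested penalty, `thresh = 1e-12`, no internal
standardization; all-constant feature matrices fall back to the closed-form
intercept-only fit.

## Known limitations

- The CNN engine is deliberately minimal (fixed 3 × 3 kernels, stride-1
  convolutions, the exact pooling layout above); it is not a general deep
  learning framework.
- Single-threaded CPU training limits practical model sizes; the standard
  5-block/1024-channel configuration is provided and correct but slow to
  train at realistic data scales.
- The 78-frame time-mapping convention and the 172-frame measured receptive
  field disagree; both are exposed, and downstream MAD values use the
  convention unless told otherwise.
- WAV support covers integer PCM (8/16/24/32-bit) and float-32 RIFF files;
  compressed codecs and streaming capture are out of scope.
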