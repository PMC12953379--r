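---
title: "Methods: wearable cardiorespiratory sleep staging and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable cardiorespiratory sleep staging and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Manual sleep staging assigns one of five labels to every 30-s epoch of a
night from EEG/EOG/EMG. Cardiorespiratory staging replaces the EEG with
signals a comfortable wearable can record continuously — here a chest
patch's single-lead ECG and three-axis accelerometer — and exploits the
coupling between sleep state and the autonomic nervous system: heart
rate, heart-rate variability, respiratory rate and regularity, and the
strength of respiratory sinus arrhythmia all vary systematically across
wake, light (N1/N2), deep (N3) and REM sleep. `cardiosleep` implements
the full chain: respiratory-waveform derivation from accelerometry, a
whole-night transformer/CNN staging model, a leave-one-subject-out
(LOSO) transfer-learning harness, agreement and sleep-architecture
statistics, and a synthetic cohort simulator that makes every stage of
the chain testable without clinical data.

## Deriving respiration from chest accelerometry

Chest-wall breathing movement appears in the accelerometer as a small
(~0.01 g) oscillation superimposed on the ~1 g gravity vector, whose
direction in the device frame depends on lying posture.

The classical derivation projects the acceleration onto the plane
perpendicular to a low-passed gravity estimate and takes the first
principal component of the in-plane motion, window by window. Its blind
spot is geometric: motion parallel to gravity is removed, and in supine
posture the breathing axis is close to gravity-parallel. The
`ORIENTATION_ROBUST` mode therefore drops the geometric projection:
the quasi-static component (gravity + posture) is removed by
subtracting a zero-phase low-pass (cutoff `gravity_lp_hz`), the residual
is band-passed to the breathing band, and the first principal axis is
found in the full 3-D windowed covariance. This is the minimal change
that removes the perpendicularity assumption while keeping the windowed
principal-axis character of the base method; both modes share all other
machinery, so the contrast between them isolates the geometry.

Parameters that matter (all in `extraction_config()`):

* `band_low_hz = 0.08`, `band_high_hz = 0.8` Hz — 4.8 to 48
  breaths/min, generous around the adult resting range;
* `gravity_lp_hz = 0.04` Hz — slow enough to pass breathing untouched,
  fast enough to re-acquire gravity within ~75 s of a posture change;
* `window_sec = 30`, `overlap_frac = 0.5` — the scoring-epoch timescale,
  with Hann-weighted overlap-add so window joins are seamless.

Numerical choices: principal-axis sign is arbitrary, so each window's
axis is flipped to have non-negative dot product with its predecessor
(the first window makes its largest component positive) — this prevents
mid-night waveform inversion. A rank-deficient window covariance falls
back to the previous window's axis. Zero-phase filtering uses
odd-reflection padding; without it, the ~1 g DC offset produces large
start-up transients. Interior gaps up to 5 s are linearly interpolated;
longer gaps are zero-filled and flagged (nights with any gap over 30
min are excluded upstream). The output is polyphase-resampled by the
exact rational ratio onto the model's respiratory grid of 307,200
samples per 10 h.

## The staging model

The model maps a fixed 10-h window — 1,200 epochs — to per-epoch
four-class posteriors, in four stages:

1. **Signal encoders.** One residual ladder per modality; each block is
   three kernel-3 convolutions with per-channel normalization and ReLU,
   a projection skip connection, and factor-2 max pooling. The ECG
   ladder (8 blocks, features 16,16,32,32,64,64,128,128) reduces
   1,228,800 samples (34.13 Hz) to 4,800 frames; the respiratory ladder
   (6 blocks, 16,32,64,64,128,128) reduces 307,200 samples (8.53 Hz) to
   the same 4,800 frames. A final kernel-1 convolution doubles the last
   block's 128 channels to the 256-channel encoder output; this
   channel-doubling head is our design choice to reconcile the
   block-feature ladder with the documented 4,800 × 256 encoder output
   width.
2. **Per-epoch fusion.** The 4 frames belonging to each epoch are
   concatenated (1,200 × 1,024) and reduced by a shared dense layer to
   128 features per epoch. Modalities are then summed; when a modality
   is absent, a learned null vector takes its place — chosen over
   concatenation so the ECG-only and ECG+respiration pathways share one
   set of downstream weights.
3. **Epoch mixer.** Sinusoidal positional encoding plus two post-norm
   transformer encoder blocks (8 heads, feed-forward width 512 = 4 ×
   128, dropout 0.1) attending over all 1,200 epochs. Head count and
   feed-forward width are standard transformer ratios (the reference
   architecture leaves them unstated); both are configurable.
4. **Sequence mixer.** Twelve dilated kernel-7 convolution layers
   (dilations 1,2,4,8,16,32 repeated twice, 128 features, residual
   connections, length-preserving zero padding) followed by a dense
   128 → 4 head. The analytic receptive field is
   1 + (7−1)·(1+2+4+8+16+32)·2 = 757 epochs — over six hours of
   context per decision, enough to encode position within the night and
   within a sleep cycle.

Normalization placement follows common practice where the reference
leaves it open: per-channel normalization over time inside the
convolutional blocks, layer normalization in the transformer. Because
nights are processed one at a time (whole nights are the batch unit),
the conv-block statistics are per-sequence (instance-norm semantics),
which makes evaluation deterministic. Weights use He fan-in
initialization under a recorded seed; two builds from the same seed are
bit-identical.

Both the forward pass and the analytic backward pass are implemented in
the package (BLAS matrix operations plus small C++ kernels for the
dilated convolutions, normalization and pooling). The backward pass is
verified against central finite differences through the entire network
in the test suite.

## Training, early stopping, LOSO

`fit_model()` minimizes cross-entropy over the four classes, masked so
that ARTIFACT (expert-unscorable) and PAD (window-filling) epochs
contribute exactly zero gradient. The optimizer is AdamW (decoupled
weight decay, default 0.01 — unstated in the reference, kept
configurable). Gradients are averaged over `batch_size` whole nights
(gradient accumulation). After each pass over the training set the
validation loss is evaluated; training stops when it has failed to
improve *strictly* on its running minimum for `patience = 5` consecutive
evaluations, and the weights revert to the minimum-validation-loss
state. "No decrease for 5 consecutive epochs" is read with standard
patience semantics; the rule is factored into `early_stopping_plan()`
and unit-tested against hand traces.

`make_loso_splits()` gives each participant one turn as the test
subject and splits the remainder into validation (`max(2, ceiling(n/6))`
participants — the 10/2 split at 13 participants) and training.
`run_loso()` audits that no test-participant night ever reaches the
optimizer. Transfer learning is a full fine-tune from a checkpoint (no
frozen layers — the reference does not mention freezing, and full
fine-tuning is the default practice it cites).

## Evaluation conventions

* Agreement (accuracy, Cohen's κ) is computed over epochs whose
  *expert* label is one of the four classes; ARTIFACT and PAD epochs
  never enter performance metrics.
* TIB is the scored-window duration — this pipeline has no lights-off
  annotation, since the device is self-applied at home. ARTIFACT epochs
  count toward TIB (the participant was in bed) but never toward TST
  (they are not scored sleep). SOL is measured from the start of the
  scored window to the first sleep-stage epoch.
* Stage percentages are expressed relative to TST, the conventional
  reading of "%N3 of sleep"; the denominators are documented so TIB- vs
  TST-based comparisons stay interpretable.
* Cohort contrasts use paired two-tailed t-tests with one value per
  participant (nights averaged first, so participant clustering cannot
  inflate the degrees of freedom). Consistency of performance across
  participants is compared via a paired t-test on squared deviations
  from the cohort mean — invariant to adding a constant to either
  condition. Zero-variance difference vectors are reported as
  degenerate rather than producing spurious statistics.

## The synthetic cohort simulator

The simulator exists so that the full pipeline — extraction, staging,
LOSO transfer, trend analysis — can be exercised and regression-tested
with no external data. It emulates, by construction:

* **Hypnogram structure.** A first-order Markov chain on the 30-s grid
  whose default transition matrix is tuned so its stationary stage
  fractions approximate the label mix of home-monitored insomnia
  cohorts scored from frontal electrodes (wake ≈ 12%, N1/N2 ≈ 32%,
  N3 ≈ 35%, REM ≈ 20%); a geometric sleep-onset wake run (mean
  `sol_min`, truncated at four times its mean); an ultradian cycle
  clock (period `mean_cycle_min` ≈ 90 min) that up-weights REM entries
  in the last 35% of each cycle and down-weights them elsewhere, with a
  REM-pressure factor that grows when a full cycle passes without REM;
  and N3 front-loading that decays N3 entries across cycles. The
  gating factors are centred to average ≈ 1 over a night, so long-run
  stage fractions still match the base chain's stationary distribution
  (verified against an eigendecomposition oracle within ±5 pp).
* **Cardiorespiratory coupling.** ECG is a template beat train — only
  inter-beat-interval statistics carry stage information, since staging
  models consume rhythm rather than morphology. Per epoch, RR
  intervals are Gaussian around the stage mean (defaults 65/60/55/62
  bpm for wake/N1N2/N3/REM) with stage SD (60/40/25/70 ms), plus a
  respiratory-sinus-arrhythmia sinusoid locked to the respiration
  phase (largest in deep sleep) — giving the model both rate-level and
  coupling cues. Respiration runs at 14/15/13/16 breaths/min with
  stage-dependent irregularity (REM highest). These defaults are
  synthetic conventions, editable in one place
  (`inst/extdata/default_physiology.yaml`), not measured clinical
  values.
* **Posture and artifacts.** A piecewise-constant gravity unit vector
  drawn from supine/lateral/prone orientations with exponential holding
  times (exercising the orientation-robustness contrast), chest-wall
  displacement of 0.01 g along a fixed device axis, motion bursts
  during wake, and white sensor noise.
* **Longitudinal structure.** Night labels B1, I1–I7, F1; time in bed
  restricted by `srt_tib_restriction_min` on I1 with linear relaxation
  so F1 is unrestricted; %N3 drifting by `n3_trend_per_night` across
  the intervention week. Because the realized %N3 of a finite,
  cycle-modulated night responds less than one-for-one to a
  stationary-calibrated gain (REM pressure pushes back), the per-night
  gain targets are corrected by a Monte-Carlo-estimated response ratio
  so injected trends come out at face value.

What the simulator does **not** emulate: realistic ECG morphology or
its artifacts, apnea/arousal events, electrode-contact dropout,
inter-participant physiology differences beyond the RNG, or scorer
disagreement. Passing tests on synthetic cohorts therefore demonstrate
that the pipeline's machinery is correct and that the model can exploit
cardiorespiratory coupling when present — they do not certify clinical
staging performance, which can only be established against
expert-labeled recordings.

## Desk-scale study conditions

The test suite and `scripts/acceptance.R` train a width-reduced
configuration (`reduced_model_config()`: 2-h windows of 240 epochs, ECG
at 256 samples/epoch over six encoder blocks, respiration at 64
samples/epoch over four, 32 features per epoch) on a 48-night synthetic
cohort (12 participants × 4 nights; 10 train / 1 validation / 1 test
participant), scratch learning rate 10⁻³, batch 8, up to 15 epochs.
These sizes are the package's chosen desk-scale study conditions: large
enough that held-out agreement clears κ > 0.3 by a wide margin against
a chance level of κ ≈ 0, small enough to rerun routinely. The transfer
contrast fine-tunes that model on a cohort generated under a genuinely
reordered autonomic convention (`shifted_physio_params()`: REM heart
rate near wake levels, beat-to-beat variability highest in light sleep,
RSA strongest in REM, respiratory rates reordered, rotated respiratory
axis). Reordering — rather than merely offsetting — the stage-to-cue
mapping guarantees a real domain gap: the base model's agreement on the
shifted cohort drops to chance level regardless of the random draw,
which offset-only shifts did not reliably produce. Fine-tuning uses
learning rate 3 × 10⁻⁴ with accumulation batches of 2 nights for 6
epochs (4 train / 1 validation / 1 test participants) — smaller batches
because only 8 nights are available per pass, and a learning rate
matched to a scratch-trained rather than converged large-scale starting
point. Improvement is assessed directionally over 10 fine-tuning seeds;
at this desk-scale budget adaptation is partial (agreement recovers
from below-chance toward, not to, in-domain levels), which is exactly
the directional claim the check makes. The %N3-trend recovery check uses a 100-participant
label-only cohort so the slope's sampling error (≈ 0.13 pp/night) sits
well inside the ±0.3 recovery tolerance.

## Known limitations

* The orientation-robust derivation is this package's concrete design;
  field devices may implement different recursive variants of the same
  idea. All of its free parameters are isolated in
  `extraction_config()`.
* Residual-block internals (activation order, norm placement) follow
  common practice for the cited encoder family rather than a published
  layer table; the channel-doubling encoder head is likewise a
  reconciliation choice, documented above.
* Whole-night batching makes conv normalization per-sequence; models
  trained with large cross-night batches would see slightly different
  statistics.
* The hand-written training stack is CPU-oriented; it is not intended
  for NSRR-scale pretraining, which the architecture's provenance
  assumes but this package deliberately leaves out of scope.
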