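# cardiosleep

Four-class sleep staging (wake, N1/N2, N3, REM) from the signals an
adhesive chest patch records in the home: single-lead ECG and three-axis
accelerometry at 125 Hz. The package is aimed at sleep researchers who
want to track sleep architecture longitudinally — for example across a
sleep-restriction-therapy protocol — without polysomnography, and at
methods developers who need a fully synthetic, reproducible test bed for
cardiorespiratory staging pipelines.

## What it does

1. **Respiration from accelerometry (ACC-RESP).** A chest patch has no
   respiratory channel. `extract_resp()` derives one from the
   accelerometer by band-passing the acceleration to the breathing band
   (0.08–0.8 Hz) and projecting 30-s windows onto their first principal
   axis. Two modes are provided: the classical *gravity-plane* method
   first projects onto the plane perpendicular to the local gravity
   estimate — and is therefore blind to chest motion parallel to gravity
   (supine breathing) — while the *orientation-robust* mode finds the
   principal axis in the full 3-D covariance and recovers breathing in
   any posture. Output lands on the model's exact respiratory grid,
   307,200 samples per 10 h (8.53 Hz).

2. **Whole-night staging model.** A sequence-labeling network that maps
   a 10-h window (1,200 30-s epochs) to per-epoch stage posteriors:
   per-modality residual convolutional encoders (ECG: 8 blocks, features
   16,16,32,32,64,64,128,128; respiration: 6 blocks, 16,32,64,64,128,128;
   three kernel-3 convolutions + max-pool per block) produce 4,800 × 256
   feature maps; frames are regrouped per epoch (1,200 × 1,024) and
   reduced to 128 features/epoch by a time-distributed dense layer;
   modalities are fused by summation (a learned null vector stands in
   for a missing channel); two transformer encoder blocks attend over
   all 1,200 epochs with sinusoidal positional encoding; a dilated
   convolution stack (kernel 7, dilations 1,2,4,8,16,32 × 2, receptive
   field 757 epochs) emits 4-class logits per epoch. Forward *and*
   backward passes are implemented in R on BLAS matrix operations with
   small C++ kernels for the convolutions — no deep-learning framework
   is required.

3. **Training and transfer.** `fit_model()` minimizes masked
   cross-entropy (ARTIFACT and PAD epochs contribute zero gradient) with
   AdamW, whole nights as the batch unit, early stopping after 5
   non-improving validation epochs, and reversion to the best-validation
   weights. `run_loso()` wraps leave-one-subject-out cross-validation
   (each participant tested once; remaining participants split into
   training and validation) for both from-scratch training and transfer
   learning from a checkpoint.

4. **Evaluation.** Confusion matrices over scored epochs, accuracy and
   Cohen's κ, sleep-architecture metrics (TST, TIB, SE, SOL, stage
   percentages of TST), paired two-tailed t-tests on per-participant
   metrics, a squared-deviation consistency test, and tidy longitudinal
   trend tables (mean ± SEM per night label B1, I1–I7, F1).

5. **Synthetic cohort simulator.** Because home-monitoring datasets of
   this kind are rarely shareable, `generate_cohort()` renders entire
   longitudinal cohorts from first principles: hypnograms from a
   cycle-modulated Markov chain (sleep-onset latency, ultradian REM
   gating, N3 front-loading), ECG as a template beat train with
   stage-dependent heart rate, beat-to-beat variability and respiratory
   sinus arrhythmia, and accelerometry as posture gravity + chest-wall
   displacement + wake motion bursts, with injectable intervention
   effects (time-in-bed restriction, per-night %N3 drift).

## Worked example

```r
library(cardiosleep)

# simulate one night and derive the respiratory channel
hyp <- generate_hypnogram(hypnogram_params(), duration_hr = 2, seed = 1)
rec <- generate_night(hyp, physio_params(), seed = 1)
rec$resp <- extract_resp(rec$accel)

# breathing rate during the night
br <- estimate_breath_rate(rec$resp)
median(br$brpm, na.rm = TRUE)
#> [1] 14

# sleep architecture from the hypnogram
sleep_metrics(hyp)
#>   tst_min tib_min   se_pct sol_min pct_n1n2   pct_n3 pct_rem
#> 1   101.5     120 84.58333    13.5 44.33498 33.00493 22.6601

# stage the night with a (here untrained) reduced model
cfg <- reduced_model_config()
inp <- resample_to_model_grid(rec, grid_for_config(cfg))
model <- build_model(cfg, seed = 1)
post <- predict_stages(model, inp)
dim(post$logits)
#> [1] 240   4
```

`sleep_metrics()` reports minutes for TST/TIB/SOL, percent for sleep
efficiency, and stage shares as percent of total sleep time. An
untrained model emits near-uniform posteriors; see the methods vignette
(`vignettes/cardiosleep-methods.Rmd`) for the training protocol that
reaches substantial agreement (κ > 0.3, far above the chance level
κ ≈ 0) on held-out synthetic participants.

## Command line

A thin CLI over the same functions ships in `inst/cli/cardiosleep`
(after installation:
`system.file("cli", "cardiosleep", package = "cardiosleep")`):

```sh
cardiosleep simulate --participants 4 --nights 2 --seed 3 --out raw/
cardiosleep extract-resp --in raw/P01_B1.edf --out resp.csv
cardiosleep preprocess --in raw/ --out prep/ --epochs 240
cardiosleep train-loso --cohort prep/ --out fit/
cardiosleep evaluate --pred pred.csv --truth truth.csv --out metrics.json
```

Waveforms travel as EDF, hypnograms and predictions as CSV, metric
reports as JSON; every artifact directory carries a provenance sidecar
(tool version, seed, configuration hash).

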