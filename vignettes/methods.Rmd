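---
title: "Subject-independent motor-imagery decoding: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-independent motor-imagery decoding: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decoding problem

A motor-imagery brain-computer interface must decide, from a short
multi-channel EEG epoch, which movement a user imagined. Classifiers trained
per user need a calibration session; the *subject-independent* setting
instead trains on a pool of other subjects and deploys on a new user with
zero calibration. The obstacle is inter-subject variability: the spatial
mixing of cortical sources into electrodes differs across heads, and raw
time-domain waveforms do not transfer.

`midecode` implements a spatial-spectral feature front end plus a
dual-branch convolutional network:

1. **Band-pass** each epoch to 8-30 Hz (order-5 Butterworth, applied
   forward-backward), the band containing the mu (~8-13 Hz) and beta
   (~14-30 Hz) rhythms that motor imagery modulates.
2. **CSP** (common spatial patterns): spatial filters `W` obtained by
   simultaneously diagonalizing the two class-average channel covariances
   `S0, S1`, i.e. `W (S0 + S1) W' = I` and `W S0 W' = diag(lambda)`. All
   `U = C` filters are kept.
3. **Covariance image**: each trial becomes the `U x U` sample covariance of
   its CSP-projected signal, min/max-scaled to `[0, 1]` with training-fold
   statistics and zero-padded (bottom/right) to a square network input.
4. **Dual-branch network**: a convolutional autoencoder branch compresses
   the image to a latent vector `z` (conv 3x3 -> batch-norm -> average-pool,
   twice, then a dense bottleneck; the decoder mirrors it with two stride-2
   transposed convolutions), while a multiscale branch applies parallel
   3x3 / 5x5 / 7x7 convolutions (10 filters each, followed by 3x3 / 20
   filters), concatenates the 60 feature maps, and maps them through
   dense(256) to a vector `m` of the same width. The classifier is a
   softmax on the elementwise sum `m + z`.
5. **Fused loss**: `beta1 * MSE(x, xhat) + beta2 * CE(y, yhat) +
   beta3 * L_center`, with weights `(0.5, 1.0, 0.5)`. The center loss
   `0.5 * sum_i ||(m_i + z_i) - c_{y_i}||^2` penalizes the distance of each
   fused feature to its class's running center, adding intra-class
   compactness to the purely inter-class softmax objective. Centers evolve
   by a damped moving average (`update_centers()`, rate `alpha = 0.5`)
   after each optimizer step, the standard non-gradient center-loss rule;
   how the centers evolve is this package's choice, as is reading the
   classifier as dense-then-softmax (a simplex vector fed *into* a dense
   layer could not yield class probabilities).

Evaluation is leave-one-subject-out (LOSO): each fold holds out one
subject entirely; CSP, the feature scaler and the early-stopping validation
split are all computed from the training subjects only.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `bandpass_spec(low, high, order)` | 8 Hz, 30 Hz, 5 | mu/beta band; order of the Butterworth prototype |
| `latent_dim` | 20 | width of `z`, `m` and the fused feature |
| `multiscale_kernels` | 3, 5, 7 | receptive fields of the parallel branch |
| `loss_weights(beta1, beta2, beta3)` | 0.5, 1.0, 0.5 | reconstruction / cross-entropy / center weights |
| `center_alpha` | 0.5 | damping of the center update |
| `initial_lr`, `batch_size` | 1e-3, 64 | Adam settings (not dictated by the method; standard defaults) |
| `lr_patience`, `stop_patience` | 5, 20 epochs | plateau decay (factor 0.5) and early stopping on validation loss |
| `val_fraction` | 0.2 | stratified trial hold-out used to monitor validation loss |

The validation set for early stopping is a stratified hold-out of pooled
training-subject trials. Holding out whole subjects instead would be
stricter but spends scarce subjects; trial hold-out is the documented
default.

"No improvement" means the validation loss failed to drop by more than
`min_delta = 1e-4`; this guards the schedule against float jitter. The
snapshot used for restoration, however, tracks any strict improvement, so
the restored parameters attain the exact minimum of the recorded validation
curve.

## Network geometry notes

* The encoder's printed average-pooling halves its input, so pooling uses
  stride 2; with a square input of side `s` (divisible by 4) the encoder
  flatten is `(s/4)^2 * 10`.
* Transposed convolutions use kernel 3x3, stride 2, same padding — the
  smallest kernels realizing the printed doubling of the decoder shapes.
* The multiscale flatten is `s^2 * 60`, the size implied by concatenating
  the three 20-filter stages; at `s = 28` this gives 47 040 and a total of
  about 12.08 M trainable parameters, within 1% of the published 12 053 956
  count (the published table prints a flatten of 15 360, inconsistent with
  its own concatenation output, so exact equality is unattainable and the
  count is treated as an approximate architecture check).
* All activations are ReLU except the softmax output. Batch normalization
  appears only in the encoder (none is listed for the multiscale branch).
* Probabilities are clipped at `1e-7` before the log in the cross-entropy.
* Weights use variance-scaling (fan-in) initialization under the run seed;
  ties in the argmax prediction resolve toward the lower class index.

## The synthetic cohort: what it emulates and what it does not

No public EEG is bundled; every stage is exercised on a synthetic
multi-subject cohort (`cohort_spec()`, `generate_cohort()`) built as a
linear forward model:

* two narrow-band sources — band-passed white noise ±2 Hz around 10 Hz
  (mu) and 22 Hz (beta) — with smooth, laterally separated scalp
  topographies shared by the cohort;
* ERD-like class structure: class 0 attenuates the mu source's amplitude by
  `class_contrast`, class 1 attenuates the beta source;
* per-subject identity: an additive Gaussian perturbation of the mixing
  matrix with entry-wise sd `subject_sigma / sqrt(C)`;
* 1/f-amplitude background noise, independent per channel, scaled to the
  source-to-noise power ratio `snr`;
* reproducibility: every (subject, trial) pair draws from its own child
  seed, so a subject's data are independent of cohort size.

Test-suite conditions: 6 subjects, 20 trials per class, 8 channels,
0.75-s epochs at 64 Hz, contrast 0.8, snr 5, `subject_sigma` 0.3. The
montage is small and the epochs short because the sources are stationary
by construction — a 0.75-s window already holds ~7 mu cycles, ample for
the covariance features — and because they keep the raw-input ablation
(whose dense layer grows with `C x T x 60`) trainable on a single CPU.
Feature images for these runs use `target_size = 12` (the 8x8 covariance
embedded in the smallest pooling-compatible square); the 28 x 28 default
corresponds to the 20-channel montages of the public datasets.

The generator deliberately omits ocular/muscular artifacts, electrode
drift, within-session non-stationarity, and inter-subject amplitude or
spectral differences — its subjects differ *only* in source mixing. Passing
tests therefore show that the pipeline recovers class structure under
controlled spatial variability; they do not certify performance on real
EEG. One consequence observed in this package's own acceptance runs: a
raw-input network generalizes across synthetic subjects far better than it
does on real data, because the amplitude patterns that carry class
information survive small mixing perturbations unchanged. The documented
advantage of the feature-based model over the raw-input ablation is
therefore smaller here than on real recordings, where temporal
non-stationarity (explicitly not simulated) is the raw model's main
failure mode.

## Numerical choices

* **Zero-phase filtering** with odd-reflection edge padding: group delay
  would shift the imagery window relative to cue onset, and unpadded
  forward-backward filtering leaves edge transients on signals with offset.
* **Resampling**: zero-phase 8th-order Butterworth anti-alias filter at 90%
  of the target Nyquist, then cubic-spline interpolation at the target
  sample times; output length `round(T * target_fs / fs)`. (The available
  polyphase resampler was rejected after it failed a DC-preservation and
  pure-tone reconstruction check.)
* **Covariance estimation**: unbiased sample covariance over time,
  per-trial trace normalization before class averaging (scale invariance
  across subjects); optional shrinkage `(1 - g) S + g (tr S / C) I`,
  default `g = 1e-6`, guards rank deficiency after channel selection.
* **CSP determinism**: filters ordered by descending class-0 eigenvalue;
  each filter's largest-magnitude coefficient is made positive. The
  feature image is permutation- and sign-sensitive for the CNN, so both
  conventions are fixed.
* **Feature scaling**: global min/max of the training-fold covariances;
  test values are clipped into `[0, 1]`. Padding sits bottom/right —
  arbitrary but fixed; same-padded convolutions see the embedded block
  identically wherever it sits.
* **Mixed precision**: during training the multiscale branch's matrix
  products (including the dominant `flatten -> dense(256)` layer) run in
  float32 through BLAS `sgemm`; master weights, the optimizer state and
  all evaluation after restoration stay double precision. Single-threaded
  runs are bit-reproducible under a fixed seed in both precisions; the
  finite-difference gradient checks run on the double path.
* **The duplicated electrode**: the published 20-name motor-cortex channel
  list for the 22-channel montage contains "C1" twice. The preset stores
  the 19 unique names plus a configurable replacement defaulting to CP2
  (the only standard electrode of the printed centro-parietal row that is
  absent). This is a repair choice of this package, not a documented
  property of the source montage.

## Problem sizes used by the test suite and acceptance script

LOSO recovery runs use the 6-subject cohort above with training capped at
60 epochs (early stopping usually ends msaenet folds sooner), three seeds
for the recovery/compactness comparisons, and one seed for the chance-level
control (`class_contrast = 0`, expected accuracy inside the 40-60% binomial
band for 240 test trials). The acceptance script repeats the full pipeline
at one seed and also recomputes the filter response, the CSP-versus-
eigendecomposition agreement on 50 random instances, and the default
architecture's parameter count. These sizes are the package's chosen test
conditions; larger cohorts only narrow the Monte-Carlo spread.

## Known limitations

* Two classes only (the CSP formulation is binary; multi-class one-vs-rest
  extensions are out of scope).
* Native readers for public dataset formats (GDF/MAT) are not included;
  convert externally into the documented HDF5 layout (`save_trials()`).
* The synthetic cohort's realism limits are listed above; in particular,
  ablation gaps measured on it need not match those on real EEG.
* Training is single-threaded by design for determinism; there is no GPU
  path.
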