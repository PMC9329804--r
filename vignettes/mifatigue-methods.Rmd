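---
title: "Motor-imagery EEG fatigue analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-imagery EEG fatigue analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`mifatigue` analyzes cued left/right-hand motor-imagery (MI) EEG with an
emphasis on mental fatigue. Five quantities are computed from a session of
epoched trials:

1. **ERD/ERS** — event-related desynchronization of the sensorimotor alpha
   rhythm on C3/C4, from Morlet time-frequency maps, with a pooled-variance
   t-test comparing time windows;
2. a **fused fatigue index** — the mean of the band-power ratios
   $(\theta+\alpha)/\beta$ and $\theta/\beta$ — with correlation-based
   selection of fatigue-sensitive parietal channels;
3. **rhythm entropy** — Shannon entropy (bits) of normalized
   $\theta/\alpha/\beta$ band-energy shares on six frontal channels;
4. **phase-locking values** (PLV) between a fatigue-sensitive parietal
   channel and the frontal set;
5. a compact three-convolution **CNN classifier** of left vs right imagery,
   fed by sliding-window/decimation augmentation.

Because no public recording accompanies the paradigm, the package ships a
synthetic-session generator whose planted parameters map one-to-one onto
the quantities the pipeline estimates; every estimator is validated by
recovering what was planted.

# The synthetic session model

A session is `n_runs` x `trials_per_run` trials (default 4 x 40 at
1,024 Hz); each trial is 3 s blank screen, 3 s video cue, and 5 s imagery,
with an event marker at imagery onset. Each channel is a sum of

* pink ($1/f$) background noise with standard deviation `noise_sd`, and
* three band-limited Gaussian oscillators (theta 4-7, alpha 8-13, beta
  14-30 Hz) with per-band amplitudes `band_amp`.

This is deliberately the *simplest* signal model whose parameters are in
one-to-one correspondence with the statistics downstream: every stage
computes a band-power or phase functional, so sums of narrowband
oscillators suffice. Three effects are planted:

* **ERD**: alpha/beta power on the contralateral motor channel (C3 for
  right-hand, C4 for left-hand trials) is multiplied by
  `1 - erd_attenuation` from `erd_onset` (default 1 s, the end of the
  preparation period) to the end of imagery. The 0-1 s baseline keeps full
  power, so the relative-change ERD estimator should recover
  `-erd_attenuation`.
* **Fatigue drift**: on `drift_channels`, band power changes linearly with
  trial index; `fatigue_drift[b]` is the fractional power change across the
  session. The fused index then rises with trial index, which is what the
  channel-selection correlation measures.
* **Phase coupling**: each configured (parietal, frontal) pair shares a
  common alpha-band oscillator with weight `sqrt(strength)` at both ends
  (plus independent remainders), making PLV a monotone function of
  `strength`, with PLV = 1 at strength 1 and trial-length chance level at
  strength 0.

What the generator does **not** emulate: volume conduction and realistic
cross-channel covariance, eye-blink/EMG artifacts (the artifact-rejection
stage is a pass-through hook), non-stationarities other than the linear
drift, and the inter-subject variability of real cohorts. Passing the
recovery tests therefore demonstrates correctness of the estimators under
the stated signal model, not clinical performance on real EEG.

The `session_preset()` profiles encode the two qualitative group signatures
the analysis is designed to detect: a "young"-like profile (moderately even
frontal band powers that concentrate into theta over the session, so rhythm
entropy falls; strong parietal-frontal coupling through P6) and an
"elderly"-like profile (theta-dominant spectrum flattening towards even
shares, so entropy rises; weak coupling through P2). The preset numbers were
chosen analytically from the share-entropy formula — the end-state shares
are strictly more (respectively less) concentrated than the start — rather
than tuned on simulations.

# Preprocessing

Filtering is a windowed-sinc (Hamming) FIR band-pass, default 1-35 Hz,
applied forward-backward (zero phase) so ERD latencies are not shifted. The
default length gives a ~1 Hz transition band; this puts DC firmly in the
stopband despite the 1 Hz lower edge, and the 50 Hz mains region is >100 dB
down after the two passes, so no separate notch is needed. The
forward-backward pass is realized in the frequency domain by multiplying
the spectrum with $|B(\omega)|^2$, which is exactly the linear convolution
with the autocorrelation of the filter taps; edge transients extend one
filter length (~3.3 s) into each end of a recording, which is why filtering
is applied to the continuous recording before epoching.

Resampling (default 512 Hz for the analysis branch) uses a zero-phase
anti-alias FIR (cutoff 0.95 of the new Nyquist) followed by decimation for
integer ratios, and Fourier resampling otherwise. Epochs span [0, 5] s from
imagery onset; the per-channel mean of the [0, 1] s preparation period is
subtracted from the whole epoch (idempotent by construction). Trials are
kept in acquisition order — the fatigue analyses depend on it.

A note on sampling rates: the classification branch consumes epochs at the
original 1,024 Hz, because the augmentation arithmetic (2 s windows of
2,048 points decimated by 4 into 512-point samples) is only consistent at
that rate — the decimation-by-4 *is* the downsampling of that branch. The
analysis branch (ERD, fatigue, entropy, PLV) uses the 512 Hz stream.

# ERD quantification

Time-frequency maps use a complex Morlet wavelet (5 cycles, 4-35 Hz at
1 Hz steps by default; the transform is implemented directly as FFT
convolution with Gaussian-spectrum kernels). Per-trial power is averaged
within a class. ERD is the baseline-relative power change
$\mathrm{ERD} = (P - \bar P_{\mathrm{base}})/\bar P_{\mathrm{base}}$
averaged over a band x window box; it is bounded below by -1, invariant to
amplitude scaling, and negative under desynchronization.

The window comparison uses a two-sample, two-tailed, pooled-variance
t-test. This exact form is pinned by a worked example: published ERD
triples for C3 ({-0.45044, -0.31794, -0.56522} vs {-0.94739, -1.0896,
-1.6016}) and C4 ({0.026749, -0.047736, 0.20375} vs {-0.51328, -0.34357,
-0.15104}) reproduce the printed significance values 0.021975815 and
0.036622313 to all digits only under equal-variance pooling with df = 4 —
Welch or one-tailed forms do not. Those triples enter the test suite as
inputs; the package makes no claim of reproducing them from raw data.

# Fatigue index and channel selection

Band extraction reconstructs the signal in each band by zero-phase
spectral masking with raised-cosine edges (1 Hz half-width). This is an
exact band-limited reconstruction at the configured edges; it was chosen
over a dyadic discrete-wavelet decomposition because the classical
theta/alpha/beta edges (4-7, 8-13, 14-30 Hz) do not fall on dyadic
boundaries at any of the involved sampling rates. Band edges are
configurable everywhere; the defaults follow the most common convention in
the fatigue literature, since published band statements vary by 1-2 Hz.

The composite index fuses the two classical ratio indicators as their
unweighted mean, $\big((\theta+\alpha)/\beta + \theta/\beta\big)/2$ — the
simplest fusion that preserves both components' monotonicity in fatigue and
their dimensionless units; the weight is exposed (`w`). Per-trial band
powers for the time course come from a Welch PSD (1 s Hann segments, 50%
overlap), integrated over the band edges.

Channel selection computes the Pearson correlation of the per-trial index
against trial index ("experimental time" is taken as trial order, the only
interpretation that is invariant to the rest-break schedule), one-sided:
channels with $r >$ threshold (default 0.75) are fatigue-sensitive. The
candidate set is the parietal ring P1-P8. Constant series get $r = 0$.

# Rhythm entropy

Per trial and frontal channel (F3, F4, F5, F1, F2, F6): band energies
$\mathrm{Power}_j = \sum_i S(x)_i^2$ of the band-reconstructed signal,
shares $p_j = \mathrm{Power}_j / \sum_k \mathrm{Power}_k$, and entropy
$En = -\sum_j p_j \log_2 p_j \in [0, \log_2 3]$ with $0 \log 0 = 0$. The
"estimated cortical activity" is the band-reconstructed channel signal
itself (no source localization), and the same band extraction is shared
with the fatigue index. The awake/fatigue contrast averages En over the
first 20 and last 20 trials in acquisition order.

# Phase-locking value

Phases come from the analytic signal (frequency-domain Hilbert transform)
of the alpha-band-filtered signal; the band is configurable since the
published analysis does not state it, and alpha is where the generator
plants coupling. The first and last 10% of each trial are discarded against
filter and Hilbert edge effects. PLV is computed exactly as
$\mathrm{PLV} = |\langle e^{i(\phi_x - \phi_y)} \rangle_t| \in [0, 1]$,
per trial, then averaged over trials — per-trial averaging avoids the
spurious phase jumps that concatenating trials would introduce. For
independent phases the expected PLV is $\sqrt{\pi}/(2\sqrt{n})$, which the
Monte-Carlo tests verify.

# The CNN classifier

The classifier is a compact three-convolution network on 1 x 32 x 512
inputs (channels x time), with the 32 channels rearranged so that the left
hemisphere occupies rows 1-15, the midline rows 16-17, and the right
hemisphere rows 18-32 — spatial convolution kernels of height 2 with
height-stride 2 then combine neighbouring electrodes without mixing the
hemispheres until deeper layers.

| layer | maps | output | kernel | stride | padding | parameters |
|-------|------|--------|--------|--------|---------|-----------|
| conv1 | 16 | 32 x 256 | 1 x 24 | 1 x 2 | 0 x 11 | 400 |
| conv2 | 32 | 16 x 256 | 2 x 11 | 2 x 1 | 0 x 5 | 11,296 |
| pool (avg) | 32 | 8 x 64 | 2 x 4 | 2 x 4 | | 0 |
| conv3 | 32 | 4 x 64 | 2 x 5 | 2 x 1 | 0 x 2 | 10,272 |
| pool (avg) | 32 | 2 x 16 | 2 x 4 | 2 x 4 | | 0 |
| flatten | | 1,024 | | | | 0 |
| dense | | 2 | | | | 2,050 |

Each convolution is followed by batch normalization and an ELU activation;
spatial dropout (rate 0.25, zeroing whole feature maps) follows each
pooling stage. Design notes on points where sources conflict or are
silent:

* **Padding.** The layer table's paddings (0x11, 0x5, 0x2) are authoritative
  — only they reproduce the printed output sizes, e.g.
  $(512 + 22 - 24)/2 + 1 = 256$ — although the accompanying prose says "no
  padding".
* **Batch normalization** carries no learnable affine parameters: the layer
  table lists 0 parameters for its rows, and the per-layer counts above
  then sum to 24,018. A printed total of 24,022 attributes 4 parameters to
  the softmax, which a standard parameter-free softmax cannot reproduce;
  the implementation uses the standard softmax and asserts the per-layer
  counts.
* **Optimizer.** Unspecified upstream; the package defaults to Adam
  (learning rate 1e-3, batch 64), softmax cross-entropy, all configurable,
  with a fixed seed giving bit-identical training runs.

Augmentation expands each 5 s trial into 12 samples: 2,048-point windows
starting at 0, 1 and 2 s, each split into its 4 interleaved
every-4th-point sub-series (phases 0-3), then globally standardized
(sample mean 0, SD 1). Decimated samples contain only original data
points. The 80/20 train/test split is grouped by parent trial — all 12
children of a trial land on one side — so 160 trials yield 1,920 samples
split 1,536/384 and the test set never shares a trial with training.

The network — convolution layers, batch-norm, pooling, spatial dropout,
Adam — is implemented in this package: the im2col assembly of the
convolution forward/backward passes is compiled C++ (delegating the matrix
products to BLAS through Armadillo), everything else is vectorized R. The
backward pass is verified against numerical differentiation in the test
suite.

# Numerical choices and problem sizes

* Spectral band masks use raised-cosine edges of 1 Hz half-width; hard
  masks would ring.
* The Morlet transform zero-pads to the next power of two of twice the
  epoch length to keep the FFT convolution linear.
* Welch segments of exactly 1 s make band powers comparable across the two
  sampling rates in use.
* `erd_quantify` errors on zero baseline power rather than returning an
  unbounded ratio; `instantaneous_phase` errors on an identically zero
  narrowband signal (undefined phase).
* Pearson correlation of a constant series is defined as 0 in channel
  selection.
* Test-suite problem sizes: recovery tests run 40-trial single-run
  sessions at 256 Hz on a 12-channel montage; the augmentation-arithmetic
  checks use the full 160-trial layout at 1,024 Hz on the 32-channel
  subset; CNN demonstrations train on a 40-trial strongly separable
  session (480 augmented samples, trial-grouped 384/96 split, 8-10
  epochs). "Strongly separable" means 95% alpha/beta attenuation applied
  across the whole imagery window at low background noise, so that every
  augmented window is informative and a linear band-power classifier on
  C3/C4 alone separates the classes — the oracle the CNN is required to
  match. These sizes are the package's chosen demonstration scale — large
  enough for the planted effects to dominate sampling noise, small enough
  to run on a laptop core in minutes.

# Known limitations

* The generator's independence across channels (apart from planted
  coupling) makes the classification task easier than real EEG; CNN
  accuracy on synthetic sessions says nothing about accuracy on real
  recordings.
* EDF I/O quantizes to 16 bits over each channel's observed range; the
  lossless internal container should be preferred for intermediate
  artifacts.
* The ICA-based artifact-rejection stage of a real pipeline is represented
  by a documented pass-through hook, since synthetic sessions are
  artifact-free; the conventional retention rule (keep components with
  >= 60% probability of being brain EEG) is noted in the hook's
  documentation for users running real data.
* Rhythm entropy with k = 3 bands is coarse by construction; its value is
  in the awake-vs-fatigue contrast, not in absolute terms.
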