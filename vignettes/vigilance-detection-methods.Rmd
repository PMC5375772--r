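---
title: "Methods: wavelet band-pass, spectral features, and SVM vigilance classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet band-pass, spectral features, and SVM vigilance classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the signal model, the processing pipeline, and the
numerical choices made in `eegvigil`, in enough detail to reimplement every
stage. The package detects drowsiness ("vigilance decline") in scalp EEG one
second at a time: wavelet denoising, per-second spectral band powers, and a
soft-margin support vector machine (SVM).

## 1. The physiological signal model

At sleep onset the occipital EEG shows a characteristic spectral shift:
theta (4--8 Hz) and alpha (8--14 Hz) power increase while beta (14--34 Hz)
power decreases. The classifier exploits exactly this shift; everything else
in the pipeline exists to make those three numbers measurable in a noisy
recording.

The recorded signal is modelled as

$$x(t) = s_\theta(t) + s_\alpha(t) + s_\beta(t) + b(t) + a(t),$$

where the $s$ terms are band-limited rhythms, $b(t)$ is broadband $1/f$
background activity, and $a(t)$ collects artifacts: ocular (blink) pulses
below ~4 Hz on the prefrontal channels and electromyographic (EMG) bursts
above ~30 Hz. The denoiser's job is to remove $a(t)$ and as much of $b(t)$
as lies outside 4--64 Hz without touching the rhythms.

## 2. The synthetic generator

Because labelled drowsy EEG cannot ship with a package, `generate_recording()`
synthesizes recordings with known per-second vigilance labels. It emulates
the *spectral statistics* of the two states, not cortical dynamics: there is
no cross-channel coherence model, no sleep-spindle or K-complex morphology,
and no gradual alert-to-drowsy transition — state changes are instantaneous
at schedule boundaries. Within those limits each ingredient is physically
motivated:

* **Rhythms** — each band is a sum of 48 sinusoids with uniformly random
  frequencies inside the band and random phases, scaled to an exact target
  RMS amplitude. Default alert occipital amplitudes are 3 (theta), 6 (alpha)
  and 4 (beta) µV RMS; prefrontal channels use 2.5/3/3.5 µV and are
  *identical across states*, so only occipital channels carry class
  information, as in real sleep-onset EEG.
* **State contrast** — `default_profiles()` applies +6 dB to theta and alpha
  and −3 dB to beta in the drowsy state (amplitude factor $10^{\mathrm{dB}/20}$).
* **Amplitude modulation** — every rhythm is modulated by a slow
  (0.05--0.5 Hz) envelope of depth 0.4, normalized to unit mean square so the
  RMS contract still holds exactly. This gives per-second feature variance,
  which is what makes accuracy *grow* with the averaging window r instead of
  saturating immediately.
* **Alpha bursts** — drowsy alpha arrives partly in 1.5-s Hann-gated bursts
  (6 per minute, amplitude multiplier 2). The tonic drowsy alpha base is
  divided by $\sqrt{1 + d(m^2-1)}$ (burst duty cycle $d$, multiplier $m$) so
  the long-run drowsy alpha RMS still equals the profile value.
* **Artifacts** — biphasic blink pulses (0.3--0.5 s, 50 µV, 12/min) on
  Fp1/Fp2 only; EMG bursts (30--100 Hz, 0.2--1 s, 8 µV RMS, 6/min) on all
  channels, *identical in both states* so artifacts can never become an
  accidental class cue.
* **Background** — $1/f$ noise (exponent 1, 4 µV RMS) built by FFT spectral
  shaping, flattened below 0.5 Hz with the DC bin zeroed.

Channels are seeded independently and deterministically
(`seed` and the channel's fixed montage index), so a channel's waveform does
not depend on which other channels were requested.

## 3. Wavelet denoising

`denoise()` runs a six-level discrete wavelet transform with the Daubechies-5
(10-tap) filter pair and symmetric (half-point) boundary extension, then
reconstructs from detail levels D3--D6 only. At 512 Hz the detail level $j$
spans the dyadic band $[f_s/2^{j+1}, f_s/2^j)$:

| level | band (Hz) | rhythm |
|-------|-----------|--------|
| D3 | 32--64 | high beta / low gamma |
| D4 | 16--32 | beta |
| D5 | 8--16  | alpha |
| D6 | 4--8   | theta |

Discarding A6 and D1--D2 removes blink energy (< 4 Hz) and EMG energy
(> 64 Hz) respectively. No coefficient thresholding is applied — the
denoiser is purely a dyadic band-pass, so it is linear, and
reconstruction from complementary level sets is exactly additive.
Keeping *all* levels reconstructs the input to machine precision
(round-trip error < 1e−8 is asserted in the test suite; observed ~1e−14).

Dyadic bands have gradual roll-offs: a 10 Hz tone keeps 99.3% of its energy
after denoising, but only 79.5% of its *coefficient* energy sits in D5 (the
rest leaks mostly into D4/D6). Band-edge leakage also slightly compresses
measured state contrasts toward 1; the feature bands below absorb this
because they are computed from the FFT of the reconstructed signal, not from
wavelet coefficients.

## 4. Spectral features

`extract_features()` computes, for each second of the denoised signal:

1. a Hanning-windowed periodogram of that one-second epoch, corrected for
   window power ($P_k = |X_k|^2 / (N \sum w^2)$, one-sided doubling), with a
   floor of 1e−12 before taking $\log_{10}$ — so an all-zero band reads
   exactly −12, never −Inf;
2. band powers $\log_{10} \sum_{f_k \in B} P_k$ over half-open bands
   theta $[4, 8)$, alpha $[8, 14)$, beta $[14, 34)$ Hz (the linear powers
   are summed, then logged);
3. the feature vector at time $t$ with window r: the mean of the log band
   powers over seconds $t-r, \dots, t$ (r + 1 epochs). Averaging in the log
   domain means the feature is the log of a *geometric* mean of band powers,
   which stabilizes the heavy-tailed power distribution.

Features are scaled to $[-1, 1]$ by min--max scaling fitted on training data
only (`scale_features()`); a constant column maps to 0.

## 5. Classification

`svm_train()` solves the soft-margin SVM dual by sequential minimal
optimization (SMO), implemented in C++: working pairs chosen by maximum
$|E_1 - E_2|$ with deterministic fallback sweeps, an error cache, and the
bias recomputed at the end as the mean over free support vectors
($0 < \alpha_i < C$), falling back to all support vectors. Labels are
+1 = alert, −1 = drowsy; a decision value of exactly 0 classifies as drowsy,
the fail-safe direction for a safety monitor. Defaults: RBF kernel
$\exp(-g\lVert x - x'\rVert^2)$ with $C = 8$, $g = 1$, KKT tolerance 1e−3.

Because consecutive seconds are serially dependent, random-split
cross-validation would leak information. `cross_validate()` therefore uses
*contiguous blocks* (default 3 folds): each fold holds out one unbroken
time segment. A training block that contains only one class is skipped with
a warning rather than silently mis-fit. `grid_search()` sweeps
$C \in 2^{\{-5,-3,\dots,15\}}$, $g \in 2^{\{-15,-13,\dots,3\}}$ (the
conventional base-2, step-2 grid) and breaks accuracy ties toward the
smallest $C$, then the smallest $g$ — preferring the least complex model.

## 6. Evaluation

With drowsy as the positive class, `r_sweep()` reports, per window length r,

* accuracy $= (TP + TN) / (TP + TN + FP + FN)$,
* sensitivity $= TP / (TP + FN)$ (drowsy seconds caught),
* false-positive rate $= FP / (FP + TN)$ (alert seconds flagged),

pooled over all held-out blocks (micro-averaged), plus the raw confusion
counts and per-second prediction timing. On the default synthetic study
(six alternating 300-s blocks, channel O1) accuracy rises monotonically in
expectation from ~77% at r = 0 to ~96% at r = 4 — larger r trades detection
latency for reliability, since a window of r seconds delays the feature's
response to a state change by up to r seconds.

Two calibration checks guard against self-deception and are part of the
test suite: with the drowsy profile replaced by the alert profile
(no class signal at all), cross-validated accuracy must sit at chance
(0.4--0.6); and the alternating schedule keeps each contiguous fold
class-balanced, without which the null calibration itself would be biased.

## 7. Design decisions and open parameters

Choices the method leaves open were resolved as follows:

* **Smoothing = feature window.** The r-second smoothing is implemented as
  the feature-averaging window itself (one model per r), not as
  post-hoc smoothing of a single model's outputs.
* **Log-domain averaging** over r (geometric mean of powers), as above.
* **3-fold leave-one-block-out** as the default CV, matching
  train-on-sessions / test-on-session practice at small fold counts.
* **Problem sizes** in examples and tests (30-minute studies, 300-s blocks)
  are this package's own choices, sized so every stage runs in seconds.
* **Tie-breaking toward drowsy** at a decision value of 0.

Known limitations: the generator's stationary-within-state model makes the
problem easier than free-running EEG; dyadic band edges do not align exactly
with the rhythm band edges (e.g. alpha [8, 14) vs D5 [8, 16)); and the EDF
writer targets the minimal subset of the format needed for round-tripping
(1-second records, 16-bit, identical rate on all channels).
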