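---
title: "Directed connectivity analysis for mobile four-channel EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed connectivity analysis for mobile four-channel EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gpdcpipe analyzes ambulatory EEG recorded with a four-electrode dry headset
(channels TP09, AF07, AF08, TP10 at 220 Hz), together with triaxial head
acceleration at 50 Hz and a per-electrode contact-quality indicator at 10 Hz.
Its goal is to contrast two behavioral conditions ("Preparation" and
"Generation" sessions) in terms of directed functional connectivity
(generalized partial directed coherence, gPDC), band power (multitaper PSD),
and signal regularity (sample entropy), with a cleaning chain designed for
the motion and contact artifacts that dominate mobile recordings.

Because recordings of this kind are rarely shareable, the package ships a
synthetic-session generator with known ground-truth directed coupling, so
that every stage of the pipeline is testable end to end: artifact detection
against planted artifacts, connectivity estimation against the generating
model, and the stage statistics against null and planted-effect cohorts.

## The generative model and the synthetic cohort

Sessions are simulated from a stable multivariate autoregressive (VAR)
process $x(t) = \sum_{k=1}^{p} A_k x(t-k) + \varepsilon(t)$ with Gaussian
innovations $\varepsilon \sim \mathcal N(0, \Sigma)$. Directed coupling is
planted as a single off-diagonal entry of a lag matrix: an edge
$j \to i$ with strength $a$ sets $A_k[i,j] = a$. Stability is verified via
the companion-matrix spectral radius and unstable requests are refused. The
VAR output is rescaled to a 20 µV per-channel RMS, the amplitude regime in
which the 100 µV voltage-jump rejection threshold is meaningful.

Corruptions emulate the artifact classes the cleaning chain targets:

* a 60 Hz line-noise sinusoid (default 5 µV in the validation cohorts);
* motion bursts: broadband noise with a Tukey (raised-cosine ramp) envelope,
  a fixed random spatial pattern across the four channels, amplitude 500 µV,
  co-occurring with a 3 m/s² spike on the accelerometer — motion artifacts
  switch on and off quickly, which the flat-middle Tukey envelope captures
  better than a slow sinusoidal ramp;
* contact dropouts: the indicator reads 3 ("bad") over planted intervals.

The accelerometer baseline is dynamic acceleration only (gravity excluded)
with 0.1 m/s² RMS jitter. The generator records the exact sample support of
every planted artifact, which is the ground truth for the masking recall and
false-alarm rates quoted by the test suite.

The generator emulates the *statistical* structure the analysis assumes —
stationary VAR segments with linear directed coupling plus additive
artifacts. It does not emulate 1/f spectral slopes, eye-blink or EMG
waveforms, or electrode drift; a pass on synthetic data therefore validates
the estimators and the artifact logic, not the physiological realism of any
particular recording.

## Preprocessing

The chain runs in a fixed order: notch → band-pass → artifact subspace
reconstruction (ASR) → rule-based rejection → epoch cutting.

* **Notch.** A second-order IIR notch at 60 Hz, quality factor Q = 30,
  applied forward-backward. The headset applies its notch online; we emulate
  it offline, and Q = 30 (1 Hz bandwidth at −3 dB) attenuates a pure 60 Hz
  tone by more than 30 dB while changing 10 Hz power by under 1%.
* **Band-pass.** A 4th-order digital Butterworth band-pass, 1–100 Hz,
  applied forward-backward ("zero-phase"); the effective magnitude response
  is therefore 8th-order. DC and sub-0.5 Hz drift are removed, 10 Hz
  amplitude is preserved within 2% with zero group delay.
* **ASR.** A simplified Euclidean artifact-subspace-reconstruction:
  calibration statistics (median window covariance, eigenbasis, and robust
  per-component RMS location/scale over 500 ms windows) are computed from
  the entire session; sliding 500 ms windows with 250 ms steps are
  eigendecomposed in the calibration basis, components whose RMS exceeds
  location + 10 × scale (threshold rotated into the window basis) are
  zeroed, and the window is reconstructed from the retained components with
  raised-cosine overlap-add. Whole-session calibration includes artifacts;
  the median/MAD statistics are what keeps the thresholds usable. When a
  flagged component loads > 0.75 on a single channel, reconstruction would
  amount to deleting that channel, so the channel's 250 ms subwindows are
  masked instead — with only four channels, deleting a channel outright
  would make the four-channel MVAR fits impossible.
* **Rule-based rejection** partitions the session into 250 ms subwindows. A
  subwindow is bad if any electrode's contact indicator (zero-order-hold
  upsampled to 220 Hz) is not "good" (1); if any channel's maximum absolute
  sample-to-sample difference exceeds 100 µV (an "abrupt voltage change" is
  read as a first difference; a window peak-to-peak reading is defensible
  too, but the first difference localizes the event more sharply); or if the
  dynamic acceleration magnitude exceeds 1 m/s². Dynamic acceleration
  subtracts the per-axis session median before taking the magnitude — a
  gravity-inclusive magnitude (~9.8 m/s²) would reject every sample at a
  1 m/s² threshold.
* **Usability.** A session is usable only if some contiguous run of
  all-good subwindows lasts at least 60 s. The rule is applied to the
  combined mask (contact, jump, motion, and ASR channel masking), which is
  slightly stricter than a contact-only reading of the one-clean-minute
  inclusion rule; unusable sessions are reported, never silently dropped.
* **Epochs.** 6 s epochs (1320 samples) with 50% overlap (3 s hop) are cut
  on a regular grid and kept only when every covered subwindow is good, so
  no epoch ever spans a masked region or stitches across a gap — stitching
  would break the stationarity the MVAR fits assume. A fully clean 66 s
  session yields floor((66−6)/3)+1 = 21 epochs.

## Connectivity: MVAR and gPDC

Each epoch is mean-centered per channel (not detrended) and fit by
least-squares VAR regression without intercept; the residual covariance uses
the bias-corrected divisor $n_{obs} - Cp$. The Schwarz criterion is
$\mathrm{SBC}(p) = \ln\det\hat\Sigma_p + \frac{\ln n_{obs}}{n_{obs}}\,p\,C^2$
with order-independent constants dropped. `select_order()` reports the
SBC-minimizing order over a scan, but the pipeline's analysis order is fixed
at p = 12 (54 ms of history at 220 Hz) for comparability across sessions.

From the fitted coefficients, the spectral transfer matrix is
$\bar A(f) = I - \sum_k A_k e^{-i 2\pi f k / f_s}$ and

$$\mathrm{gPDC}_{i \leftarrow j}(f) =
  \frac{|\bar A_{ij}(f)| / \hat\sigma_i}
       {\sqrt{\sum_{k} |\bar A_{kj}(f)|^2 / \hat\sigma_k^2}},$$

the residual-noise-normalized variant of partial directed coherence. The
normalization makes the measure invariant to per-channel amplitude scaling
and bounds it in [0, 1] with $\sum_i \mathrm{gPDC}^2_{i \leftarrow j}(f) = 1$
per source column — both properties are asserted to 1e-8/1e-6 in the tests.

gPDC is evaluated on a 1–50 Hz grid in 1 Hz steps (the grid is a package
choice; results are reported over 1–50 Hz). One MVAR is fit per epoch and
gPDC magnitudes are averaged pointwise across epochs (the short-time
stationary approach); fitting one model to concatenated epochs was rejected
because concatenation boundaries violate stationarity. Band means aggregate
the averaged spectra over delta [1–4), theta [4–8), alpha [8–12), beta
[12–30), gamma [30–50] Hz; half-open edges prevent the shared edge
frequencies from being double-counted, and gamma keeps its upper edge.

## Spectral power and sample entropy

The PSD of each epoch channel is Thomson's multitaper estimate with
time-half-bandwidth nw = 4 (7 Slepian tapers, computed from the classical
tridiagonal eigenproblem and cached), zero-padded to nfft = 4096, with
unweighted eigenspectrum averaging (adaptive weighting is available nowhere
in the chain and was not needed; unweighted is the simplest defensible
choice). The one-sided density integrates to the signal variance over
[0, 110] Hz (checked to 10% on white noise); the returned grid is restricted
to 1–50 Hz. Reading "4096 frequency bins" as nfft — rather than as 4096
bins inside 1–50 Hz, which would imply nfft ≈ 90,000 — is the only
physically plausible interpretation at this record length.

Sample entropy uses the Richman–Moorman conventions: template length m = 2,
tolerance r = 0.2 SD of the analyzed window, Chebyshev distance,
self-matches excluded, and both template lengths counted over the same index
range $i \le N - m$ (N = 1320, one epoch). Because r scales with the SD, the
measure is exactly invariant under affine transforms of the signal. Zero
match counts propagate as an undefined flag (NA), never as ±∞; undefined
epochs are excluded from session means per channel with the exclusion count
reported, so per-channel inclusion can differ. The compiled counting kernel
sorts templates by first coordinate and enumerates only pairs within
tolerance on it — an exact algorithm, verified identical to a brute-force
oracle on hundreds of random sequences.

## Stage statistics

The unit of analysis is the session mean of each feature. For every
metric × location × band (or PSD bin) cell, a Fisher–Snedecor F-test at
α = 0.05 decides between the pooled two-sample t-test (df = n₁+n₂−2) and the
Welch–Satterthwaite test; the comparison row carries both group means,
per-group 95% confidence intervals (mean ± t₀.₉₇₅,ₙ₋₁·s/√n — per-condition
intervals, matching how such contrasts are displayed), the F gate, the test
used, t, df, p, and a significance flag at α = 0.05. The F-gate level is a
package choice (the gate itself is standard; its level is rarely stated).
No multiple-comparison correction is applied by default, matching the
uncorrected-p convention of the small-cohort literature this pipeline
serves; a Benjamini–Hochberg flag is available but off by default.
Contiguous runs of significant PSD bins are additionally summarized as
frequency ranges per channel. Cells with fewer than two sessions per stage
are emitted with a skipped flag rather than dropped.

## Numerical choices and degenerate inputs

* Filters: `signal::butter`/`signal::filtfilt`; the 1–100 Hz band at a
  220 Hz rate puts the upper edge at 0.91 of Nyquist, verified stable.
* ASR windows that trigger no flags reconstruct to the input exactly
  (orthogonal basis round trip); overlap-add weights are sin² ramps that
  sum to one at 50% overlap, with explicit renormalization at the edges.
* `fit_mvar` refuses rank-deficient regressor matrices and epochs with
  $n_{obs} \le Cp$; `sbc` falls back to an eigenvalue log-determinant when
  the Cholesky factorization fails, and errors only for singular residual
  covariances.
* Zero-variance channels make gPDC undefined and raise an error naming the
  degenerate channel; constant signals make sample entropy undefined (NA).
* All generation is a pure function of (specification, seed): per-session
  seeds derive deterministically from the master seed, and re-running the
  pipeline with the same configuration reproduces every CSV byte for byte.

## Validation problem sizes

The test suite and the acceptance script validate at sizes chosen to make
the statistical assertions sharp while staying desk-scale: coefficient
consistency at N = 50,000 samples; order recovery on 100 epoch-length
records; directionality recovery on 100 preprocessed 66 s sessions (the
planted direction's band mean must exceed the reverse in all five bands);
type-I calibration on four null cohorts of 20 + 20 sessions (about 2,100
comparison cells, significant fraction expected near 0.05); artifact recall
and false-alarm rates on 90 s sessions over several seeds. The vignette
states no empirical number that those runs do not themselves compute.

## Known limitations

* Scalp-level only: four channels support no source localization, and gPDC
  edges are statistical, not anatomical, statements.
* The ASR variant is Euclidean and window-local; the Riemannian variant and
  ICA-based cleaning are out of scope.
* No hierarchical modeling: sessions are treated as independent units, with
  no participant-level random effects.
* The synthetic generator's linear-Gaussian world cannot detect estimator
  biases that only non-linear or non-stationary physiology would reveal.
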