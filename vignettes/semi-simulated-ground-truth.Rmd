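---
title: "Semi-simulated ground truth for fNIRS: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-simulated ground truth for fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsynth)
library(ggplot2)
```

## The problem this package addresses

Evoked hemodynamic responses in functional near-infrared spectroscopy
(fNIRS) are small relative to the physiology they ride on: scalp blood
flow, cardiac pulsation, Mayer waves, respiration, slow drifts, and motion.
New de-noising and single-trial detection methods therefore need benchmark
data in which the brain response is *known*. The semi-simulation approach
takes real (or realistically simulated) resting-state recordings — which
contain all the confounds and none of the evoked activity — and adds a
synthetic hemodynamic response function (HRF) of known shape, timing,
amplitude, and channel membership directly in the raw intensity domain.
Any processing pipeline can then be scored against exact ground truth.

`nirsynth` implements that generator end to end: a resting-state
simulator, the calibrated HRF injection, SNIRF v1.0 file I/O with
per-channel ground-truth flags, the standard quality metrics (channel SNR,
motion ratio), and reference recovery pipelines (block averaging and a GLM
with short-separation nuisance regression).

## The HRF model

The injected kernel is a peak-normalized gamma shape

$$h(t) = \left(\frac{t}{t_p}\right)^{a}
         \exp\!\left[a\left(1 - \frac{t}{t_p}\right)\right],
  \qquad 0 \le t \le T,$$

with time-to-peak $t_p = 6$ s and total support $T = 16.5$ s. Only $t_p$
and $T$ are externally constrained; the shape parameter $a$ is a free
choice of this package. We use $a = 10$, for which the truncation residual
$h(T) \approx 6\times10^{-4}$ is below 0.1% of the peak, so cutting the
kernel at 16.5 s introduces no visible discontinuity. `hrf_kernel()`
rejects shapes whose residual exceeds that bound rather than silently
truncating a fat tail. The kernel is sampled on the closed grid
$0, 1/f_s, \dots, T$ (826 samples at 50 Hz), making the length contract
unambiguous.

```{r kernel, fig.width = 5, fig.height = 3}
autoplot(hrf_kernel())
```

## Amplitude calibration

The 100% amplitude level is *defined* in the intensity domain: a peak
fractional change of +1% at 690 nm and −2% at 830 nm. Injection is
multiplicative,

$$I'(t) = I(t)\,\bigl[1 + f_\lambda\, h(t - t_{\text{onset}})\bigr],$$

because a fractional statement stays true under a drifting baseline, which
an additive injection would not respect. Through the modified Beer–Lambert
law (MBLL) with a differential pathlength factor (DPF) of 6 at both
wavelengths and a 3 cm source–detector separation, those intensity changes
correspond to concentration peaks of roughly +0.66 µM oxyhemoglobin
(HbO~2~) and −0.23 µM deoxyhemoglobin (HbR):

```{r calib}
calibrate_amplitude(100)
```

With the extinction table shipped here (the Gratzer/Prahl compilation used
throughout the Homer ecosystem, decadic convention,
`inst/extdata/extinction_gratzer.csv`) the exact inversion gives
+0.645/−0.204 µM. Published variants of these nominal peaks differ at the
few-hundredths-of-a-µM level depending on the coefficient table; we treat
±0.05 µM as the agreement band and expose the table as a user-replaceable
CSV. The 50% and 20% levels scale the *reference* concentration peak
linearly (not the logarithm), so `conc_peak(50)` is exactly half of
`conc_peak(100)` — the small multiplicative-injection nonlinearity
(≈0.5–1% at these amplitudes) is attributed to the injection, not to the
calibration.

## The augmentation scheme

`plan_augmentation()` reproduces the published recipe:

* the recording is cut into consecutive **20 s windows** (a trailing
  partial window gets no trial — this keeps the no-overlap guarantee
  unconditional), so 5- and 10-minute recordings yield 15 and 30 trials;
* one onset per window is drawn **uniformly from 0–3.5 s** after the
  window start. 3.5 + 16.5 = 20, so consecutive responses can never
  overlap;
* targets are drawn once per recording: half (`floor`) of the
  **long-separation** pairs whose channels both pass a **5 dB SNR**
  pruning threshold, where SNR = 20·log10(mean/sd) of raw intensity;
* the onset stream is shared by all augmented channels (a single
  experimental paradigm), matching the per-channel *constant*
  ground-truth flag the file format uses: a channel either carries HRFs
  in every window or in none.

Both draws come from one user seed via `withr::with_seed`, so a plan — and
through it the augmented file — is byte-reproducible. `apply_plan()`
leaves non-selected channels, auxiliaries, and the probe bit-identical,
adds one stimulus channel named `HRF_<level>` with `(onset, 16.5 s, 1)`
events, and sets `dataTypeLabel = 1` on augmented channels. The three
published amplitude variants (100/50/20%) are produced by three calls with
the seeds of your choice; onsets are shared across levels exactly when the
seeds are.

## The resting-state simulator

The simulator is a first-class module, not a test shim: it produces
recordings with the structure every downstream stage assumes, at the two
published probe scales (`dataset1`: 5 min, 26 long + 2 short pairs, full
multimodal auxiliary set; `dataset2`: 10 min, 48 + 8, accelerometer only),
at 50 Hz and 690/830 nm.

Channels are multiplicative fluctuations around a constant baseline
intensity: cardiac pulsation (1.1 Hz), respiration (0.25 Hz), Mayer waves
(0.1 Hz) — each a phase-jittered sinusoid so the rates wander as real ones
do — plus an integrated-noise (1/f-like) drift and white measurement
noise, each channel with independent drift/noise. The systemic trio is
*shared*: short-separation channels carry it at unit weight, long-separation
channels at `systemic_coupling` (default 0.5), and the cardiac/Mayer phases
reappear in the PPG and blood-pressure auxiliaries. That shared structure is
what makes short-separation regression testable. Motion events (off by
default) are simultaneous intensity steps and accelerometer excursions.

No quantitative noise levels are published for the real recordings, so the
default amplitudes (cardiac 1.0%, Mayer 0.8%, respiration 0.5%, drift
1.0%, white noise 0.3% of baseline) are this package's own choice, set so
that channel SNRs land around 28–42 dB — the range a practitioner would
call typical for good-contact continuous-wave data — which keeps the 5 dB
pruning rule meaningful when the noise knobs are raised. What the
simulator deliberately does **not** model: photon transport through real
head geometry, heterogeneous per-channel coupling (losing a channel to bad
contact), spatially structured scalp physiology, serially correlated
measurement noise, or subject-level variability. Tests passing on these
simulations therefore demonstrate *mechanistic correctness* of the
generator and pipelines, not performance claims about real data.

## Quality metrics

Channel SNR is `20 * log10(mean/sd)` of raw intensity. Motion detection
follows the classic Homer channel-wise detector's parameter semantics
(`tMotion = 0.5 s`, `tMask = 0.5 s`, `STDEVthresh = 20`, `AMPthresh = 5`),
re-specified here because the reference implementation is code, not a
formula: within each sliding `t_motion` window a channel is flagged when
the largest sample-to-sample change exceeds `stdev_thresh` times the
channel-wide standard deviation of the change signal, or the raw excursion
(max − min) exceeds `amp_thresh`. The std criterion is applied to the
*change* signal deliberately: a smooth oscillation's windowed range is of
order $f_s/2$ times its per-sample change, so testing the raw range
against `sd(diff)` would flag any clean sinusoid regardless of amplitude.
The seed of a flagged window is its steepest sample; `[seed, seed +
t_motion]` is masked and dilated by `±t_mask`, so an isolated step at
$t_0$ masks exactly $[t_0 - t_{mask},\, t_0 + t_{motion} + t_{mask}]$.
This is Homer-compatible in spirit, not bit for bit. By default detection
runs on optical density, which makes `amp_thresh` comparable across
channels; raw intensity is available via `domain = "intensity"`. The
motion ratio is the flagged fraction of acquisition time.

## Recovery pipelines and numerical choices

The reference stream mirrors standard baseline analysis: a zero-phase
low-pass at 0.5 Hz (3rd-order Butterworth run forward and backward —
effective order 6 — with odd-reflection padding to suppress edge
transients), MBLL conversion per source–detector pair using each pair's
own geometric separation, then either:

* **block averaging** — epoch at onsets, subtract the onset sample,
  average; or
* **GLM** — ordinary least squares on stimulus-convolved Gaussian bases
  (centers every 1 s on [0, 16.5] s, sd 1 s; a common Homer-style choice,
  as no basis width is externally fixed), an intercept + polynomial drift
  of degree 3, and the short-separation series of the matching chromophore
  as nuisance columns (demeaned; constant columns dropped). The temporally
  embedded CCA regressor construction used in the original analyses is
  separately published prior work and is intentionally out of scope; plain
  short-separation regression is the reference nuisance model here.

Rank deficiency raises an error naming the collinear columns rather than
silently pseudo-inverting. On noise-free fixtures the GLM recovers the
injected peak to well under 1%, and block averaging reproduces the
concentration-domain kernel to <1% relative RMS — the residual is the
multiplicative-injection nonlinearity plus the ~1% passband droop of the
double Butterworth pass at HRF frequencies, which is why `fc = NULL`
(filter off) is used for exactness checks.

Problem sizes used in the shipped tests — e.g. ten noisy 300 s preset-I
replicates for the recovered-amplitude check, 60–120 s fixtures for
exactness properties — were chosen as the smallest sizes at which the
statistical assertions are stable.

## Degenerate inputs and tie-breaks

* Zero-separation channels are a geometry error, not a "short" channel.
* A constant channel has infinite SNR and always survives pruning; a
  nonpositive-mean channel yields `NaN` SNR with a warning.
* An odd pruned-pool size augments `floor(n/2)` pairs.
* Level 0 is a valid amplitude: injection is the identity, flags stay 0.
* Recordings shorter than one window, onset ranges that would spill past
  the window, and empty stimulus designs are refused with specific errors.

## Known limitations

* The simulator's realism limits are listed above; in particular,
  recovered-amplitude statistics on simulation should not be read as
  predictions for real-head data.
* The SNIRF writer covers the continuous-wave subset used by this data
  layout (one data block, stim/aux/probe, per-channel `dataTypeLabel`);
  frequency- and time-domain NIRS types and multi-block files are out of
  scope.
* The motion detector matches the named Homer parameters' semantics, not
  the reference implementation sample for sample.
* MBLL here uses two chromophores and a wavelength-shared DPF default;
  partial-volume or wavelength-dependent pathlength corrections are not
  modeled.
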