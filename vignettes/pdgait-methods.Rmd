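---
title: "pdgait: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pdgait: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pdgait)
```

This vignette documents the scientific and numerical choices behind the
package: the data model of the wearable network, the synthetic gait and
packet-loss generators, the quality-control conventions, the walking
classifier, and the gait descriptors. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The data model

Five tri-axial accelerometers (belt, left/right wrist, left/right leg)
sample at 62.5 Hz — exactly 16 ms per sample, which makes integer
millisecond timestamps exact — with a ±6 g full scale. Axis convention:
x = cranio-caudal (vertical during upright stance), y = medio-lateral,
z = anterio-posterior. The radios provide no retransmission; every packet
carries a unique timestamp, and loss is detected at the receiver purely
from timestamp gaps. The CSV interchange dialect
(`sensor_id,timestamp_ms,ax_g,ay_g,az_g`) is this package's own standard:
the original logger format is not public. Accelerations are written with
17 significant digits so a write/read round trip is bit-exact.

## Synthetic gait

`simulate_gait_acceleration()` needs to produce signals whose *statistical
structure* matches what the downstream estimators assume, with closed-form
ground truth. It is **not** a biomechanically validated forward model of
parkinsonian gait.

* **Vertical displacement.** Each step's vertical centre-of-mass
  displacement is a raised-cosine arc of amplitude `h`
  (`com_excursion_m`, default 0.05 m, a typical adult value): continuous
  across steps, peak-to-trough exactly `h`, and with an analytic second
  derivative that becomes the cranio-caudal acceleration (plus a constant
  1 g gravity offset on belt and leg sensors). Double integration
  therefore recovers `h`, and the inverted-pendulum step length
  `s = 2·sqrt(2·l·h − h²)` is exact ground truth.
* **Harmonics.** Real gait acceleration carries strong harmonics. These
  are placed on the anterio-posterior (z) channel (2nd/3rd harmonic at
  −12 dB) and a stride-frequency sway on y — *not* on x. Putting them on
  x would perturb its double integral by up to ~3% and break the package's
  own invariant that the noiseless x-channel reproduces `h` within 2%;
  the z-channel also follows the gait cycle, so the realism is preserved
  where it does not distort the ground truth.
* **Stride timing.** Stride (two-step) intervals are i.i.d. log-normal
  with mean `2/step_frequency_hz` and coefficient of variation
  `stride_time_cv`; log-normal keeps intervals positive and `cv = 0`
  degenerates to exactly equal intervals. Each stride is split into two
  equal steps. Healthy default cv 0.02; PD-like default 0.10.
* **Asymmetry.** Left/right steps scale `h` by `1 ± asymmetry/2`
  (healthy default 0.05, PD-like 0.15).
* **Noise.** White Gaussian noise (`harmonic_noise_sd`, default 0.04 g
  healthy / 0.08 g PD-like) on every channel. No sensor specification was
  available; the defaults were chosen once so that plotted traces
  resemble published belt recordings, and are ordinary config knobs.
* **Other activities.** `simulate_session()` fills resting intervals with
  gravity plus 0.015 g device noise, and `arm_task` intervals add
  broadband amplitude-modulated transients to the wrists only. The
  transients are deliberately *aperiodic* (smoothed-envelope-times-noise):
  desk activities have no gait-band rhythm, which is what lets a
  spectral classifier reject them.

## Packet loss

Disconnections arrive as a Poisson process (default 0.1 events/s/sensor);
each removes the 4-sample logger-reconnect minimum (64 ms) plus a
geometric number of extra samples (default mean 2), and a start-up burst
(default 5 s) removes the head of every stream — deployments show the
longest bursts always at session start. The geometric extension has its
mode at zero, so the modal burst is 64 ms for *any* rate, matching field
observations. Expected sporadic loss is
`rate·(4 + extra_mean)/62.5`; `loss_model_for_percent()` inverts this so a
stream can be calibrated to a published per-patient loss percentage
(defaults give ≈ 1%, the middle of the published 0.32–2.02% range).

## Quality control conventions

* `detect_gaps()` reports leading and trailing loss too, so the
  conservation law `expected = received + missing` holds exactly on every
  stream; the property suite enforces it.
* Loss percent is reported as mean ± sd over fixed 60 s analysis windows
  within the session. Published tables print "mean ± sd" without defining
  the spread; windows-within-session is this package's interpretation and
  the window length is configurable.
* Burst statistics use the *population* sd (deterministic on tiny lists,
  0 for a single burst) and an exact-value mode — durations live on the
  16 ms grid, so no binning is needed; ties break toward the smallest
  duration.
* `trim_startup()` discards everything before the first gap-free
  `stable_s` window (default 10 s — the rule comes from deployment
  practice, the constant is this package's choice) and re-bases
  timestamps to zero. A stream with no stable window fails QC rather than
  being silently analysed.

## Preprocessing

Features operate on **raw g values**. The familiar `[0, 1]` display
normalisation (`(a + 6)/12`) exists for plotting/export parity only:
entropy tolerances and double integration are scale-sensitive, and the
normalisation is affine anyway. Gap policy: interior gaps up to 4 samples
(one reconnect burst) are linearly interpolated and masked; anything
longer splits the recording — the pipeline never fabricates more than
64 ms of data. Only the sensors the analysis actually consumes (legs +
belt by default) force splits.

## Walking segmentation

Windows of 2.56 s (160 samples, FFT-friendly at 62.5 Hz) with 50% overlap
slide over the leg-sensor acceleration modules. Four transparent features
per window: log10 variance, dominant frequency in 0.5–3 Hz, gait-band
power ratio, and absolute inter-leg correlation. The classifier is a
ridge-regularised logistic score (IRLS with fixed iterations, so fitting
is deterministic even under perfect separation) rather than an opaque
learner; the shipped coefficients were fitted once on a seeded synthetic
fixture (`walking_training_windows()`, seed 101, five walker profiles
spanning slow/fast/healthy/PD) and are frozen in
`default_walking_model()`. A test refits the fixture and checks the
frozen numbers.

Windows straddling an activity transition have no well-defined label, so
ground-truth labelling (`label_windows()`) assigns the majority label with
its purity and declines to label windows below 0.75 purity; accuracy is
scored over labelled windows only. This was decided before any accuracy
was measured. Merging absorbs single negative windows inside a run and
drops segments shorter than 10 s — short bouts cannot support entropy or
variability estimation anyway.

## Gait descriptors

* **Sample entropy** uses the Richman–Moorman counting convention
  (self-matches excluded, both template lengths counted over the `N − m`
  templates that admit a continuation), Chebyshev distance, defaults
  `m = 2`, `r = 0.2·sd`, computed on the raw-rate cranio-caudal belt
  channel of the segment. Which channel the original system fed to
  entropy is not public; channel and parameters are config keys. The
  implementation is an O(N²) C++ kernel; the test suite holds it exactly
  equal to an exhaustive R oracle. Degenerate inputs: a constant series
  returns 0 (flagged); zero match counts return `Inf` (flagged) instead
  of raising.
* **Filtering.** All filtering is zero-phase FFT filtering with
  raised-cosine transition bands (half-width 50% of the cutoff) and
  even-reflection padding sized to the slowest cutoff. An IIR Butterworth
  was considered, but no filter-design package is available in the target
  environment and brick-wall FFT filtering rings; the smooth-transition
  zero-phase filter measured distortion-free on in-band tones and is
  fully deterministic. The even reflection matters: odd (point)
  reflection injects a DC step at the pad whenever the edge sample is
  nonzero, which a high-pass turns into a large edge transient.
* **Step detection**: band-pass 0.5–3 Hz, spectral estimate of the step
  rate, peak picking with a quarter-period minimum separation, parabolic
  sub-sample refinement. A rhythmicity guard (≥ 30% of gait-band power
  within ±0.25 Hz of the dominant peak) rejects non-walking input with an
  explicit reason instead of emitting garbage steps.
* **Stride-time CV**: stride intervals are alternate-step differences,
  but the stride parity is unobservable; the wrong parity averages
  adjacent strides and shrinks CV by ≈ 1/√2, so the parity with the
  larger CV is reported. Recovery is within 15% of the simulated CV at
  ≥ 200 strides in the test suite.
* **Stride length**: x-channel → m/s², high-pass 0.1 Hz, trapezoidal
  integration, high-pass again after each stage, per-step peak-to-trough
  `h` between consecutive step events (steps within 1.5 s of the segment
  edge excluded), `h` clipped to `(0, l]`, then the pendulum formula. On
  noiseless simulations the recovered mean step length is within 5% of
  ground truth (≈ 0.3% in practice). With default noise the max–min
  estimator acquires a positive bias of roughly 5–10% on `h` — noise
  peaks add to the true extremes — which is documented rather than hidden
  because no published bound constrains the noisy case. `leg_length_m`
  is a required per-subject input; no anthropometry is bundled.
* **Velocity** is the segment-mean product `f·s̄` (the instantaneous
  reading of "velocity" was rejected: cadence and step length are only
  stable at segment scale), with a consistency flag.

## What a green test does and does not establish

The generator reproduces the *assumed statistics* (band-limited periodic
gait, controllable variability/asymmetry/noise, Poisson-plus-geometric
loss with a reconnect minimum). It omits, among other things: postural
transitions, turning, freezing episodes, tremor's specific 4–6 Hz
signature, sensor orientation drift, and any correlation between sensors'
loss processes. Accuracy figures on synthetic data (e.g. the ≥ 99%
walking classification) therefore validate the pipeline's machinery and
internal consistency, not clinical performance; equivalence with the
original deployed classifier cannot be claimed because its features and
training data are not public.

## Numerical details worth knowing

* Population vs sample sd: burst statistics use population sd; windowed
  loss uses population sd across windows; stride CV uses sample sd.
* Ties in the burst-duration mode break toward the smaller duration.
* All simulators take explicit integer seeds and are bit-reproducible;
  sessions derive per-interval seeds from the session seed.
* The per-window loss report flags `sd_undefined` when the stream is
  shorter than one window; the empty burst list yields a sentinel report,
  not an error.
* YAML configuration was narrowed to JSON: no YAML parser is available in
  the target environment, and JSON round-trips the full config.
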