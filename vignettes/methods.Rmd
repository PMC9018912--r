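---
title: "Methods: stepwise DBS beta suppression and its behavioural readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stepwise DBS beta suppression and its behavioural readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(betadose)
```

This vignette is the package's account of its science: the generative model
behind the synthetic sessions, the analysis pipeline applied to them, the
parameters that matter, and the design choices made where the design was
genuinely open. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The recording model

A session emulates a streamed sensing-IPG recording during a monopolar
review: one bipolar subthalamic LFP channel at 250 Hz, a per-sample
stimulation-amplitude trace in mA, and machine-readable annotations
(`rest`, `tap_block`, `stim_step:<mA>`, `ramp_down`) on a half-open
`[onset, onset + duration)` time axis. `make_protocol()` lays the session
out: amplitudes 0, 0.5, ..., max mA and a trailing OFF step; per step 60 s
rest then 2 tapping blocks of 10 s separated by 10 s; a 23 s linear
ramp-down before the final OFF step (defaults; all configurable).

The LFP is a sum of:

* **aperiodic background** — spectrally shaped noise with power
  `~ f^-chi`, `chi = 1.3` by default (typical for bipolar LFP in the
  5-45 Hz range), clamped below 1 Hz;
* **narrowband oscillators** — filtered white noise with Gaussian spectral
  profiles rather than pure tones, so the signal *bursts* like
  physiological beta and wavelet estimates carry realistic sampling
  variance. Beta sits at the hemisphere's individual peak (12-19 Hz,
  3 Hz bandwidth); theta (6.5 Hz) and alpha (10 Hz) are control bands;
* **artifacts** — 50 Hz line noise; optionally a triangular 80 ms QRS train
  (cardiac bleed-through) and a narrow tone at 94 Hz with the character of
  stimulation aliasing;
* **white measurement noise**.

Component amplitudes are RMS values in µV. The defaults
(`beta_amp0 = 1.5`, `aperiodic_amp = 0.35`, `noise_sd = 0.25`, theta/alpha
0.4/0.5) make the beta oscillator carry most of the band power at rest.
This is a deliberate idealization: the dose-response acceptance checks
require the measured band power to track the oscillator across a ~30 dB
suppression range, which a realistic aperiodic floor would truncate. The
consequence is that absolute normalized band powers run higher than
typical patient values; the *shape* of the dose-response, the washout and
the coupling to behaviour are unaffected. See §7.

## 2. Dose-response and washout

At stimulation amplitude `I` the beta oscillator's amplitude is multiplied
by `m = exp(-k I)` (`k = suppression_k`, per mA), instantaneously at step
onset. Beta *power* therefore follows `exp(-2 k I)` and log band power is
linear in dose with slope `-2k`. The default `k = 0.83` makes that slope
-1.66 per mA.

Washout: during the brief ramp-down the modulation holds at the last
stimulated level (sub-therapeutic amplitudes are treated as still
suppressing); from the moment stimulation reaches 0 mA it relaxes as
`m(t) = 1 - (1 - m0) exp(-t / tau)`. The recovery time constant is not
separately observable in the source data — only the time at which low-beta
power re-crosses a fraction of baseline is. `recovery_tau_for_crossing()`
therefore calibrates `tau` in closed form so that the *measured* ratio
crosses 0.8 at a target time (13 s by default), correcting for the share
`b` of low-beta band power carried by the background
(`ratio = (1 - b) m^2 + b`, with `b` computed from the generator's own
spectral masks via `expected_band_power()`). The default
`recovery_tau_s = 6.2` s is this calibration evaluated at the default
protocol and ground truth.

## 3. Movement model and velocity quantification

Tapping acceleration is a 3 Hz sinusoid on the z-axis inside tap blocks,
scaled so the integrated velocity amplitude equals the block's true
velocity `v0 (1 + c (1 - m_block))` — the more beta is suppressed, the
faster the tapping (`c = velocity_coupling_c`, default 1.4, chosen so that
full suppression roughly doubles velocity). Outside blocks the axis is
white noise.

Analysis side, `velocity_trace()` converts acceleration to a velocity
measure: remove sub-0.5 Hz drift, integrate, rectify, smooth with a
100-sample moving average, z-score over the whole recording (n-1
denominator). The acceleration-to-velocity transform is not specified in
the field's descriptions; numerical integration of the detrended signal is
the plainest reading and makes the scaling exactly linear, which the tests
verify. A second, block-level smoothing kernel is reported in the source
literature as 10^7 samples — physically impossible at 250 Hz and treated
as a typo; block values are simple means of the smoothed trace inside each
annotated block. Z-scoring makes everything invariant to accelerometer
hardware gain, at a price: ratios of z-scored velocities are not ratios of
physical velocities, so relative velocities are interpretable only as a
monotone proxy (the per-step *ranks* are preserved, which is what the
tests assert).

## 4. Spectral estimation choices

* **Morlet, 8 cycles, 1 Hz grid, 3-97 Hz.** Implemented as one-sided
  Gaussian windows in the frequency domain; power is scaled so a unit
  sinusoid yields its mean square 0.5. The convolution is evaluated only
  at the stored time grid: the map is decimated 5-fold (to 50 Hz) by exact
  spectral folding — power envelopes in this band vary far below that
  rate, and window averages are unchanged. The Gaussian window is
  truncated at 5 sigma (relative error < 1e-6).
* **Edge trim 2 s** at segment ends, beyond the 8-cycle wavelet at the
  lowest analysis frequency (~1.3 s half-length at 3 Hz).
* **Normalization denominator.** "% of total sum" is ambiguous between
  per-recording and per-segment totals; one *session-level* denominator
  (time-averaged power summed over 3-47/53-97 Hz across the whole
  recording) keeps all steps of a session on one scale, so within-session
  dose effects are not flattened by per-step renormalization. The
  conservation property (normalized time-averaged power sums to 100)
  holds by construction and is asserted to 1e-6.
* **Rest windows.** First 30 s of each step's trimmed rest interval;
  shorter intervals fall back to what is available (recorded in the
  output), below 10 s they are rejected.
* **Peak detection.** Highest local maximum above an iteratively re-fitted
  log-log linear aperiodic baseline, prominence 0.5 %-points, ties to the
  lower frequency. The baseline re-fit keeps oscillatory bumps from
  inflating the aperiodic estimate.
* **Band edges** are integer bins, inclusive; 8 and 20 Hz belong to both
  neighbouring bands, matching the conventional overlapping notation.

## 5. Artifact screening

The source procedure was visual; the package operationalizes it:

* **Cardiac contamination**: QRS trains are periodic and broadband at low
  frequencies, so the score is the peak autocorrelation (lags 0.33-2 s,
  i.e. 30-180 bpm) of the rectified 0.5-4 Hz component of the *unfiltered*
  signal. Clean sessions score ~0.1, 3x-RMS contamination ~0.6; the
  default threshold is 0.3.
* **Stimulation aliasing**: a narrow tone above 70 Hz. The Morlet map
  cannot resolve it (at 94 Hz the 8-cycle wavelet is ~12 Hz wide), so the
  screen uses a ~1 Hz-resolution smoothed periodogram
  (`periodogram_spectrum()`); the score is the largest bin-to-local-median
  ratio over 70-97 Hz, threshold 5.

Either flag excludes the hemisphere; no artifact removal is attempted,
mirroring the exclusion-based handling of real recordings.

## 6. Inference

* **Paired permutation test**: sign flips of pair differences; exact
  enumeration when `2^n <= n_permutations` (p is then the exact
  proportion), otherwise Monte-Carlo with the +1 correction. Two-sided,
  statistic = mean difference.
* **Mixed models**: `lmerTest::lmer`, ML estimation (so BICs are
  comparable across fixed-effect choices), random intercept per subject
  only, Satterthwaite p-values. The dose model logarithmizes power first —
  on the generative model this linearizes the dose-response exactly. The
  reported R² is the marginal (fixed-effects) pseudo-R²,
  `var(Xb) / (var(Xb) + var(ranef) + var(resid))`; which pseudo-R² the
  source reports is unstated, so this choice is called out prominently.
  Singular random-effect fits are flagged, not hidden.
* **Model comparison**: `delta = BIC_b - BIC_a`, "strong" iff
  `|delta| > 6`, strictly.
* **Correlations**: Shapiro-Wilk gate at alpha = 0.05 per series; Pearson
  if both pass, Spearman otherwise; the method used is recorded.
* **Recovery time**: per-second ratios of a ~3 Hz-bandwidth bursting
  oscillator have only ~6 effective degrees of freedom each, so a raw
  first-crossing rule is noise-dominated (it fires early on upward
  excursions). The default estimator fits the exponential return
  `c1 - c2 exp(-t/tau)` to the 20-point profile by least squares (grid on
  tau, linear in c1/c2) and reads the 0.8 crossing off the fitted curve;
  the raw sustained-2 s threshold rule is available as
  `method = "threshold"`. Cohort-level recovery statements aggregate the
  pointwise-mean profile across sessions before estimating the crossing.

## 7. What the simulator does and does not establish

The generator reproduces the statistical structure the analysis assumes:
exponential dose-dependent suppression of a bursting beta oscillation,
washout with first-order kinetics, velocity coupled to instantaneous beta
suppression, 1/f background, line noise, and the two artifact classes.
Passing tests therefore demonstrate that the pipeline *recovers known
structure of that kind* at realistic noise levels — parameter recovery,
calibration of test levels, monotonicity, determinism.

They do not demonstrate performance on real Percept-family exports. Known
gaps: no tremor or dyskinesia; no within-step burst-statistics dynamics
(burst parameters are a fixed bandwidth choice, not fitted to data); a
beta-dominated band power balance (see §1) flattering to dose-slope
recovery; stimulation aliasing as a single stationary tone; accelerometer
tapping as a pure sinusoid; no inter-hemispheric coupling; synchronization
between accelerometer and LFP taken from metadata rather than estimated.
The session JSON dialect is the package's own versioned schema
(`inst/extdata/session.schema.json`), not a vendor format.

## 8. Problem sizes and determinism

Simulation studies in the test suite use deliberately economical sizes:
rest windows shortened to 10-22 s (the pipeline records the actual window
used), ramp-downs of 3-5 s where washout is not under test, cohorts of
6-10 hemispheres, 5 replicate cohorts per suppression level, 100 null
replicates for test-level calibration, 20-40 seeds for detection-rate
properties, and 2000 Monte-Carlo permutations where the exact reference is
also computed. The end-to-end checks use the full default protocol.
Every stochastic step runs under an explicit seed (`with_seed()` restores
the caller's RNG state), per-hemisphere seeds derive from one master seed,
and reports rerun to byte-identical JSON.

## 9. Known limitations

* The marginal-R² convention makes the velocity-model R² depend on how
  much between-subject variance the random intercept absorbs; comparisons
  with other software should fix the convention first.
* The recovery-time estimator assumes a monotone exponential return; a
  rebound overshoot would be mis-timed (the profile itself is reported, so
  this is inspectable).
* `detect_beta_peak()` selects by absolute spectral height among
  qualifying maxima; on strongly sloped spectra with two near-equal bumps
  the lower-frequency one can win by riding the 1/f slope.
* Normalized (% total sum) quantities are compositional: strong
  suppression of a dominant band necessarily inflates the share of all
  other bands, which is visible in the control-band dose slopes on
  synthetic cohorts.
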