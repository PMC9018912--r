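#' Ground-truth parameters of a synthetic hemisphere
#'
#' Collects the generative parameters of one simulated sensing hemisphere.
#' The LFP model is a sum of (i) an aperiodic 1/f background with exponent
#' `aperiodic_exponent`, (ii) narrowband "bursting" oscillators at the
#' individual beta peak (12-19 Hz), theta (6.5 Hz) and alpha (10 Hz),
#' (iii) 50 Hz line noise, optional ECG and stimulation-aliasing artifacts,
#' and (iv) white measurement noise. The beta oscillator's amplitude at
#' stimulation amplitude I (mA) is `beta_amp0 * exp(-suppression_k * I)`, so
#' beta band power is `(beta_amp0 * exp(-suppression_k * I))^2` and
#' log-power is linear in I with slope `-2 * suppression_k`. After the last
#' stimulated step (from ramp-down onset) the modulation relaxes back toward
#' baseline with time constant `recovery_tau_s` (washout). Finger-tapping
#' velocity in a block at step I is
#' `tap_v0 * (1 + velocity_coupling_c * (1 - m))`, m being the mean beta
#' amplitude modulation during that block, plus Gaussian noise `vel_noise_sd`.
#'
#' Defaults reproduce the magnitudes of a typical bradykinetic-phenotype
#' recording: beta peak 16 Hz, dose-response log-power slope
#' -2k = -1.66 per mA, and washout timed so low-beta power re-crosses 80%
#' of baseline about 13 s after stimulation reaches 0 mA under the default
#' protocol.
#'
#' @param beta_peak_hz individual beta peak frequency, within [12, 19].
#' @param beta_amp0 baseline beta oscillator RMS amplitude (uV).
#' @param suppression_k per-mA exponential decay rate of beta amplitude, >= 0.
#' @param aperiodic_exponent 1/f background exponent (power ~ f^-exponent).
#' @param aperiodic_amp background RMS amplitude (uV).
#' @param theta_amp,alpha_amp RMS amplitudes of the control-band oscillators.
#' @param line_noise_amp 50 Hz sinusoid amplitude (uV).
#' @param ecg_bpm,ecg_amp optional cardiac artifact rate/amplitude (0 = none).
#' @param alias_hz,alias_amp optional stimulation-aliasing tone (0 = none).
#' @param velocity_coupling_c gain mapping relative beta suppression to tap
#'   velocity improvement.
#' @param recovery_tau_s washout time constant (s) of beta return to baseline.
#' @param noise_sd white measurement-noise SD (uV).
#' @param tap_v0 baseline (OFF stimulation) tap velocity, arbitrary units.
#' @param tap_rate_hz finger-tapping rate (Hz).
#' @param vel_noise_sd SD of per-block velocity noise.
#' @return a `ground_truth` list.
#' @export
ground_truth <- function(beta_peak_hz = 16, beta_amp0 = 1.5,
                         suppression_k = 0.83, aperiodic_exponent = 1.3,
                         aperiodic_amp = 0.35, theta_amp = 0.4,
                         alpha_amp = 0.5, line_noise_amp = 2,
                         ecg_bpm = 70, ecg_amp = 0,
                         alias_hz = 94, alias_amp = 0,
                         velocity_coupling_c = 1.4, recovery_tau_s = 6.2,
                         noise_sd = 0.25, tap_v0 = 1, tap_rate_hz = 3,
                         vel_noise_sd = 0.05) {
  stopifnot(beta_peak_hz >= 12, beta_peak_hz <= 19, suppression_k >= 0,
            beta_amp0 >= 0, aperiodic_amp >= 0, recovery_tau_s > 0,
            noise_sd >= 0, tap_v0 > 0, tap_rate_hz > 0)
  structure(list(
    beta_peak_hz = beta_peak_hz, beta_amp0 = beta_amp0,
    suppression_k = suppression_k,
    aperiodic_exponent = aperiodic_exponent, aperiodic_amp = aperiodic_amp,
    theta_amp = theta_amp, alpha_amp = alpha_amp,
    line_noise_amp = line_noise_amp,
    ecg_bpm = ecg_bpm, ecg_amp = ecg_amp,
    alias_hz = alias_hz, alias_amp = alias_amp,
    velocity_coupling_c = velocity_coupling_c,
    recovery_tau_s = recovery_tau_s, noise_sd = noise_sd,
    tap_v0 = tap_v0, tap_rate_hz = tap_rate_hz,
    vel_noise_sd = vel_noise_sd
  ), class = "ground_truth")
}

#' Sample per-hemisphere ground truths for a cohort
#'
#' Draws each hemisphere's parameters from ranges emulating between-subject
#' variability: beta peak uniform on 12-19 Hz (reported range of individual
#' peaks), suppression rate centred on 0.83 /mA (the dose-response
#' log-power slope of -1.66 per mA), and coupling gain centred on 1.4 (a
#' roughly two-fold velocity improvement at full suppression).
#'
#' @param n number of hemispheres.
#' @param seed integer seed.
#' @param suppression_k_range,velocity_coupling_range,beta_peak_range,
#'   beta_amp0_range uniform sampling ranges; give a length-1 value to fix a
#'   parameter across the cohort.
#' @return list of `ground_truth` objects.
#' @export
sample_ground_truth <- function(n, seed,
                                suppression_k_range = c(0.63, 1.03),
                                velocity_coupling_range = c(1.0, 1.8),
                                beta_peak_range = c(12, 19),
                                beta_amp0_range = c(1.2, 1.8)) {
  runif2 <- function(r) if (length(r) == 1L) rep(r, n) else stats::runif(n, r[1], r[2])
  with_seed(seed, {
    peaks <- runif2(beta_peak_range)
    amps <- runif2(beta_amp0_range)
    ks <- runif2(suppression_k_range)
    cs <- runif2(velocity_coupling_range)
    lapply(seq_len(n), function(i)
      ground_truth(beta_peak_hz = peaks[i], beta_amp0 = amps[i],
                   suppression_k = ks[i], velocity_coupling_c = cs[i]))
  })
}

#' Beta amplitude modulation over a session
#'
#' The deterministic multiplicative factor m(t) applied to the beta
#' oscillator: `exp(-suppression_k * I(t))` during the stepped phase,
#' held at the last stimulated step's value through the brief ramp-down,
#' then from stimulation cessation (end of ramp) an exponential return
#' `1 - (1 - m0) * exp(-(t - t_cess) / recovery_tau_s)` where m0 is the
#' modulation at the last stimulated amplitude. The washout models the slow
#' physiological return of beta after chronic-stimulation offset and is
#' decoupled from the decreasing ramp amplitude.
#'
#' @param protocol a `protocol_spec`.
#' @param truth a `ground_truth`.
#' @return numeric vector, one value per LFP sample.
#' @export
beta_modulation <- function(protocol, truth) {
  fs <- protocol$sampling_rate_hz
  I <- stim_trace(protocol)
  t <- (seq_along(I) - 1) / fs
  sched <- protocol_schedule(protocol)
  ramp <- sched[sched$label == "ramp_down", ]
  m <- exp(-truth$suppression_k * I)
  if (nrow(ramp) == 1L && truth$suppression_k > 0) {
    amps <- protocol$step_amplitudes_mA
    m0 <- exp(-truth$suppression_k * amps[length(amps) - 1L])
    cess <- ramp$onset_s + ramp$duration_s
    m[t >= ramp$onset_s & t < cess] <- m0
    idx <- t >= cess
    m[idx] <- 1 - (1 - m0) * exp(-(t[idx] - cess) / truth$recovery_tau_s)
  }
  m
}

#' Washout time constant giving a target baseline-recovery time
#'
#' Closed-form calibration of `recovery_tau_s` so that measured low-beta
#' power relative to the pre-stimulation baseline crosses a threshold ratio
#' `t_cross` seconds after stimulation reaches 0 mA (the washout clock's
#' origin). Accounts for the aperiodic + noise share `b` of measured
#' low-beta band power, which dilutes the oscillator's suppression: the
#' measured ratio is `(1 - b) * m(t)^2 + b`, so the amplitude modulation must
#' reach `sqrt((ratio - b) / (1 - b))`, giving
#' `tau = t_cross / log((1 - m0) / (1 - m_thr))`. `b` is computed from the
#' generator's own spectral masks via [expected_band_power()].
#'
#' @param protocol a `protocol_spec`.
#' @param truth a `ground_truth` (its `recovery_tau_s` is ignored).
#' @param t_cross target crossing time after cessation (s); default 13.
#' @param ratio threshold ratio; default 0.8.
#' @return time constant in seconds.
#' @export
recovery_tau_for_crossing <- function(protocol, truth, t_cross = 13,
                                      ratio = 0.8) {
  amps <- protocol$step_amplitudes_mA
  m0 <- exp(-truth$suppression_k * amps[length(amps) - 1L])
  b <- background_band_fraction(truth, band = band_definition("low_beta"))
  stopifnot(ratio > b)
  m_thr <- sqrt((ratio - b) / (1 - b))
  stopifnot(m_thr > m0, m_thr < 1)
  t_cross / log((1 - m0) / (1 - m_thr))
}

#' Expected band power of each generator component
#'
#' Analytic time-averaged power (uV^2) contributed by the generator's
#' components within a frequency band, computed from the same spectral masks
#' the simulator uses, at baseline (no stimulation). Useful for calibration
#' and oracle tests.
#'
#' @param truth a `ground_truth`.
#' @param band a `band_definition` (or NULL for total over 0-Nyquist).
#' @param fs sampling rate used for the mask grid; default 250.
#' @param n_s mask grid length in seconds; default 600.
#' @return named numeric: `beta`, `theta`, `alpha`, `aperiodic`, `noise`.
#' @export
expected_band_power <- function(truth, band = NULL, fs = 250, n_s = 600) {
  n <- fs * n_s
  f <- fft_freqs(n, fs)
  in_band <- if (is.null(band)) rep(TRUE, n) else
    abs(f) >= band$lo_hz & abs(f) <= band$hi_hz
  frac <- function(mask2) sum(mask2[in_band]) / sum(mask2)
  nb2 <- function(center, fwhm) {
    sigma <- fwhm / 2.355
    exp(-((abs(f) - center)^2) / (2 * sigma^2))^2
  }
  ap2 <- {
    fa <- pmax(abs(f), 1)
    m2 <- fa^(-truth$aperiodic_exponent)
    m2[f == 0] <- 0
    m2
  }
  c(beta = truth$beta_amp0^2 * frac(nb2(truth$beta_peak_hz, 3)),
    theta = truth$theta_amp^2 * frac(nb2(6.5, 2)),
    alpha = truth$alpha_amp^2 * frac(nb2(10, 2)),
    aperiodic = truth$aperiodic_amp^2 * frac(ap2),
    noise = truth$noise_sd^2 * mean(in_band))
}

#' Fraction of baseline band power not carried by the beta oscillator
#' @inheritParams expected_band_power
#' @return scalar in [0, 1).
#' @export
background_band_fraction <- function(truth, band) {
  p <- expected_band_power(truth, band)
  unname((p["theta"] + p["alpha"] + p["aperiodic"] + p["noise"]) / sum(p))
}

# two-sided FFT bin frequencies for length n at rate fs
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}
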