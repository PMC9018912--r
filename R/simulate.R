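#' Simulate a stepped-stimulation LFP session
#'
#' Generates one bipolar LFP channel at the protocol sampling rate following
#' the monopolar-review schedule: an aperiodic 1/f background, narrowband
#' oscillators (theta, alpha, and an individual beta peak whose amplitude is
#' suppressed as `exp(-suppression_k * I)` at stimulation amplitude I and
#' relaxes back with `recovery_tau_s` after ramp-down onset), 50 Hz line
#' noise, optional ECG and aliasing artifacts, and white noise. Narrowband
#' oscillators are amplitude-modulated filtered white noise (3 Hz bandwidth
#' for beta) rather than pure tones, emulating physiological bursting.
#'
#' Output is deterministic for a fixed `(protocol, truth, seed)` triple.
#'
#' @param protocol a `protocol_spec` from [make_protocol()].
#' @param truth a `ground_truth` from [ground_truth()].
#' @param seed integer seed.
#' @param subject_id,hemisphere identifiers stored in the session.
#' @return a `session_recording`: list with `subject_id`, `hemisphere`,
#'   `channels` (list of `list(label, samples)`), `sampling_rate_hz`,
#'   `stim_trace_mA`, `events` (data.frame onset_s/duration_s/label) and
#'   `metadata`.
#' @export
simulate_lfp <- function(protocol, truth, seed, subject_id = "sim",
                         hemisphere = "left") {
  stopifnot(inherits(protocol, "protocol_spec"), inherits(truth, "ground_truth"))
  fs <- protocol$sampling_rate_hz
  stim <- stim_trace(protocol)
  n <- length(stim)
  t <- (seq_len(n) - 1) / fs
  m <- beta_modulation(protocol, truth)

  x <- with_seed(seed, {
    bg <- shaped_noise(n, fs, function(m, fs)
      aperiodic_mask(m, fs, truth$aperiodic_exponent))
    beta <- shaped_noise(n, fs, function(m, fs)
      narrowband_mask(m, fs, truth$beta_peak_hz, 3))
    theta <- shaped_noise(n, fs, function(m, fs) narrowband_mask(m, fs, 6.5, 2))
    alpha <- shaped_noise(n, fs, function(m, fs) narrowband_mask(m, fs, 10, 2))
    phi <- stats::runif(2, 0, 2 * pi)
    wn <- stats::rnorm(n, 0, truth$noise_sd)
    truth$aperiodic_amp * bg +
      truth$beta_amp0 * m * beta +
      truth$theta_amp * theta + truth$alpha_amp * alpha +
      truth$line_noise_amp * sin(2 * pi * 50 * t + phi[1]) +
      truth$alias_amp * sin(2 * pi * truth$alias_hz * t + phi[2]) +
      wn
  })

  sched <- protocol_schedule(protocol)
  events <- sched[, c("onset_s", "duration_s", "label")]
  rownames(events) <- NULL

  rec <- structure(list(
    subject_id = subject_id, hemisphere = hemisphere,
    channels = list(list(label = "lfp_13", samples = x)),
    sampling_rate_hz = fs, stim_trace_mA = stim, events = events,
    metadata = list(seed = as.integer(seed), schema_version = "1.0",
                    generator = "betadose-simulator")
  ), class = "session_recording")

  if (truth$ecg_amp > 0)
    rec <- inject_ecg_artifact(rec, truth$ecg_bpm, truth$ecg_amp)
  rec
}

# unit-RMS real noise with the given two-sided FFT amplitude mask; the
# synthesis grid is zero-padded to a highly composite FFT length
shaped_noise <- function(n, fs, mask_fun) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  x <- Re(stats::fft(stats::fft(w) * mask_fun(m, fs), inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

# Gaussian amplitude mask centred at `center` Hz with the given FWHM
narrowband_mask <- function(n, fs, center, fwhm_hz) {
  f <- fft_freqs(n, fs)
  sigma <- fwhm_hz / 2.355
  exp(-((abs(f) - center)^2) / (2 * sigma^2))
}

# 1/f^(exponent/2) amplitude mask; clamped below 1 Hz, zero at DC
aperiodic_mask <- function(n, fs, exponent) {
  f <- abs(fft_freqs(n, fs))
  m <- pmax(f, 1)^(-exponent / 2)
  m[f == 0] <- 0
  m
}

#' Simulate the 3-axis accelerometer trace of a session
#'
#' The z-axis carries a tapping oscillation (sinusoidal acceleration at
#' `tap_rate_hz`) only inside the protocol's tap blocks; x/y and
#' out-of-block z are white noise with SD `noise_sd`. The acceleration
#' amplitude of a block at step amplitude I is scaled so the integrated
#' velocity amplitude equals the block's true tap velocity
#' `tap_v0 * (1 + velocity_coupling_c * (1 - m_block))` plus Gaussian noise,
#' `m_block` being the mean beta modulation during the block — i.e. tapping
#' speeds up as beta is suppressed.
#'
#' @inheritParams simulate_lfp
#' @param fs_accel native accelerometer rate (Hz), default 500.
#' @return an `accel_trace`: list with `sampling_rate_hz`, `x`, `y`, `z`,
#'   `start_offset_s` (0) and `metadata$blocks`, a data.frame of the true
#'   per-block velocities (step_index, step_mA, block, true_velocity).
#' @export
simulate_accelerometer <- function(protocol, truth, seed, fs_accel = 500) {
  stopifnot(inherits(protocol, "protocol_spec"), inherits(truth, "ground_truth"),
            fs_accel >= 250)
  dur <- protocol_duration(protocol)
  n <- round(dur * fs_accel)
  t <- (seq_len(n) - 1) / fs_accel
  sched <- protocol_schedule(protocol)
  blocks <- sched[sched$label == "tap_block", ]
  m_lfp <- beta_modulation(protocol, truth)
  fs_lfp <- protocol$sampling_rate_hz

  with_seed(seed, {
    x <- stats::rnorm(n, 0, truth$noise_sd)
    y <- stats::rnorm(n, 0, truth$noise_sd)
    z <- stats::rnorm(n, 0, truth$noise_sd)
    vel <- numeric(nrow(blocks))
    for (i in seq_len(nrow(blocks))) {
      on <- blocks$onset_s[i]; du <- blocks$duration_s[i]
      i_lfp <- pmin(pmax(floor(on * fs_lfp), 0), length(m_lfp) - 1):
        pmin(floor((on + du) * fs_lfp), length(m_lfp) - 1) + 1L
      m_block <- mean(m_lfp[i_lfp])
      v <- truth$tap_v0 *
        (1 + truth$velocity_coupling_c * (1 - m_block)) +
        stats::rnorm(1, 0, truth$vel_noise_sd)
      vel[i] <- v
      idx <- which(t >= on & t < on + du)
      tt <- t[idx] - on
      taper <- pmin(1, pmin(tt, du - tt) / 0.25) # 250 ms edge taper
      z[idx] <- z[idx] +
        v * 2 * pi * truth$tap_rate_hz * sin(2 * pi * truth$tap_rate_hz * tt) * taper
    }
    structure(list(
      sampling_rate_hz = fs_accel, x = x, y = y, z = z, start_offset_s = 0,
      metadata = list(seed = as.integer(seed),
                      blocks = data.frame(step_index = blocks$step_index,
                                          step_mA = blocks$step_mA,
                                          block = ave(blocks$step_index,
                                                      blocks$step_index,
                                                      FUN = seq_along),
                                          true_velocity = vel))
    ), class = "accel_trace")
  })
}

#' Add a synthetic cardiac artifact to a session
#'
#' Superimposes a periodic triangular QRS-like template (80 ms width) on all
#' LFP channels at the given heart rate. The input is not modified; a new
#' session is returned.
#'
#' @param recording a `session_recording`.
#' @param bpm heart rate, within [30, 180].
#' @param amp template peak amplitude (uV); 0 returns the input unchanged.
#' @return a `session_recording` with the artifact added.
#' @export
inject_ecg_artifact <- function(recording, bpm, amp) {
  stopifnot(inherits(recording, "session_recording"))
  if (!is.numeric(bpm) || bpm < 30 || bpm > 180)
    stop("invalid-argument: bpm must be within [30, 180]")
  if (amp == 0) return(recording)
  fs <- recording$sampling_rate_hz
  n <- length(recording$channels[[1]]$samples)
  ecg <- ecg_signal(n, fs, bpm, amp)
  out <- recording
  for (i in seq_along(out$channels))
    if (startsWith(out$channels[[i]]$label, "lfp"))
      out$channels[[i]]$samples <- out$channels[[i]]$samples + ecg
  out$metadata$ecg_injected_bpm <- bpm
  out
}

# periodic triangular QRS template train (width 80 ms), peak height `amp`
ecg_signal <- function(n, fs, bpm, amp) {
  t <- (seq_len(n) - 1) / fs
  period <- 60 / bpm
  half <- 0.04
  phase <- t %% period
  dist <- pmin(phase, period - phase) # distance to nearest beat time
  amp * pmax(0, 1 - dist / half)
}
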