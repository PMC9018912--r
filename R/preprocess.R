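#' Filter specification for LFP preprocessing
#'
#' Defaults follow the standard sensing-IPG preprocessing chain: 5th-order
#' Butterworth highpass at 5 Hz (movement artifact), lowpass at 98 Hz
#' (stimulation aliasing), and a 48-52 Hz bandstop (line noise).
#'
#' @param order Butterworth order of each stage.
#' @param highpass_hz,lowpass_hz passband edges (Hz).
#' @param bandstop_hz length-2 stopband (Hz).
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(order = 5, highpass_hz = 5, lowpass_hz = 98,
                        bandstop_hz = c(48, 52)) {
  stopifnot(order >= 1, highpass_hz > 0, lowpass_hz > highpass_hz,
            length(bandstop_hz) == 2, bandstop_hz[1] > highpass_hz,
            bandstop_hz[2] < lowpass_hz, bandstop_hz[1] < bandstop_hz[2])
  structure(list(order = order, highpass_hz = highpass_hz,
                 lowpass_hz = lowpass_hz, bandstop_hz = bandstop_hz),
            class = "filter_spec")
}

# forward-backward filtering with reflect padding (one settle length each
# side, trimmed after) — removes signal::filtfilt's edge transients
filtfilt_padded <- function(filt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 500L)
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- signal::filtfilt(filt, c(left, x, right))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth bandpass + bandstop filtering
#'
#' Applies the highpass, lowpass and bandstop stages of a [filter_spec()] in
#' cascade, each forward-backward (zero phase) with reflect padding, so the
#' output has the same length as the input and no phase distortion.
#'
#' @param samples numeric series (uV).
#' @param fs sampling rate (Hz); must exceed `2 * lowpass_hz`.
#' @param spec a `filter_spec`.
#' @return filtered series, same length.
#' @export
bandpass_bandstop <- function(samples, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (fs <= 2 * spec$lowpass_hz)
    stop("invalid-argument: fs must exceed twice the lowpass edge")
  settle <- ceiling(2 * fs) # ~2 s covers the 5 Hz highpass transient
  if (length(samples) < 3 * settle)
    stop("invalid-argument: input shorter than 3x filter settle length")
  nyq <- fs / 2
  hp <- signal::butter(spec$order, spec$highpass_hz / nyq, "high")
  lp <- signal::butter(spec$order, spec$lowpass_hz / nyq, "low")
  bs <- signal::butter(spec$order, spec$bandstop_hz / nyq, "stop")
  y <- filtfilt_padded(hp, samples, settle)
  y <- filtfilt_padded(lp, y, settle)
  filtfilt_padded(bs, y, settle)
}

#' Filter all LFP channels of a session
#'
#' @param recording a `session_recording`.
#' @param spec a `filter_spec`.
#' @return the session with every `lfp*` channel filtered.
#' @export
filter_session <- function(recording, spec = filter_spec()) {
  out <- recording
  for (i in seq_along(out$channels))
    if (startsWith(out$channels[[i]]$label, "lfp"))
      out$channels[[i]]$samples <-
        bandpass_bandstop(out$channels[[i]]$samples,
                          recording$sampling_rate_hz, spec)
  out
}

#' Score cardiac contamination of an LFP channel
#'
#' Cardiac bleed-through is screened against the delta-range activity: QRS
#' complexes put a strictly periodic train into the 0.5-4 Hz component of
#' the raw signal, where clean LFP has only aperiodic background. The score
#' is the peak of the normalized autocorrelation of the rectified 0.5-4 Hz
#' component over lags 0.33-2.0 s (180-30 bpm); the flag fires above
#' `threshold`. Run this on the unfiltered signal — the preprocessing
#' highpass removes the band the detector relies on.
#'
#' @param samples numeric series (uV), at least 20 s, unfiltered.
#' @param fs sampling rate (Hz).
#' @param threshold flag threshold on the score; default 0.3.
#' @return list with `score` and `flag`.
#' @export
detect_ecg_contamination <- function(samples, fs, threshold = 0.3) {
  if (length(samples) < 20 * fs)
    stop("invalid-argument: need at least 20 s of data")
  bp <- signal::butter(3, c(0.5, 4) / (fs / 2), "pass")
  env <- abs(filtfilt_padded(bp, samples - mean(samples)))
  max_lag <- ceiling(2.0 * fs)
  ac <- stats::acf(env, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  lags <- (seq_along(ac) - 1) / fs
  sel <- lags >= 0.33 & lags <= 2.0
  score <- max(ac[sel])
  list(score = score, flag = score > threshold)
}

#' Score stimulation-aliasing contamination of a normalized spectrum
#'
#' Aliasing of the stimulation pulse train appears as a narrow tone in the
#' upper sensed band. The score is the largest ratio, over 70-97 Hz, of a
#' bin's power to the median power of its +-5 Hz neighbourhood (the bin
#' itself excluded).
#'
#' @param spectrum a `normalized_spectrum` covering at least 70-97 Hz.
#' @param threshold flag threshold; default 5.
#' @return list with `score` and `flag`.
#' @export
detect_stim_aliasing <- function(spectrum, threshold = 5) {
  stopifnot(inherits(spectrum, "normalized_spectrum"))
  f <- spectrum$freqs_hz
  if (min(f) > 70 || max(f) < 97)
    stop("invalid-argument: spectrum must cover 70-97 Hz")
  p <- spectrum$power_pct
  sel <- which(f >= 70 & f <= 97)
  ratio <- vapply(sel, function(i) {
    nb <- which(abs(f - f[i]) <= 5 & seq_along(f) != i)
    p[i] / stats::median(p[nb])
  }, numeric(1))
  score <- max(ratio)
  list(score = score, flag = score > threshold)
}

#' Automated artifact QC for one session
#'
#' Replaces visual inspection: computes the ECG-contamination score on the
#' filtered first LFP channel and the aliasing score on the session's
#' normalized rest spectrum, and excludes the hemisphere when either flag
#' fires.
#'
#' @param recording a `session_recording` (unfiltered).
#' @param ecg_threshold,aliasing_threshold score thresholds.
#' @param cfg a `spectral_config` used for the aliasing spectrum.
#' @return a `qc_report` list: `ecg_score`, `ecg_flag`, `aliasing_score`,
#'   `aliasing_flag`, `decision` ("include"/"exclude"), `reasons`.
#' @export
qc_session <- function(recording, ecg_threshold = 0.3, aliasing_threshold = 5,
                       cfg = spectral_config()) {
  x <- recording$channels[[1]]$samples
  fs <- recording$sampling_rate_hz
  ecg <- detect_ecg_contamination(x, fs, ecg_threshold)
  # aliasing is screened on the unfiltered signal (tone intact above 70 Hz)
  # with the ~1 Hz periodogram: the Morlet map's bandwidth at 94 Hz is far
  # too wide to resolve a narrow tone against its local floor
  spec <- periodogram_spectrum(x, fs, cfg)
  al <- detect_stim_aliasing(spec, aliasing_threshold)
  reasons <- character(0)
  if (ecg$flag) reasons <- c(reasons, sprintf("ECG contamination (score %.2f)",
                                              ecg$score))
  if (al$flag) reasons <- c(reasons, sprintf("stimulation aliasing (score %.2f)",
                                             al$score))
  structure(list(ecg_score = ecg$score, ecg_flag = ecg$flag,
                 aliasing_score = al$score, aliasing_flag = al$flag,
                 decision = if (length(reasons)) "exclude" else "include",
                 reasons = reasons),
            class = "qc_report")
}
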