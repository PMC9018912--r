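#' Build a monopolar-review stimulation protocol
#'
#' Lays out the stepped-stimulation session template used during a monopolar
#' review: stimulation amplitude is increased from 0 mA in fixed steps up to a
#' maximum (the clinically tolerated amplitude), and each step holds a rest
#' recording followed by blocks of finger tapping separated by short rests.
#' After the last stimulated step the amplitude is ramped down linearly to
#' 0 mA (to avoid switch artifacts) and a final OFF-stimulation step of the
#' same rest/tap layout is recorded.
#'
#' @param max_amplitude_mA highest stimulation amplitude (mA), > 0. Amplitudes
#'   run `0, step, 2*step, ...` up to the largest multiple of `step_mA` not
#'   exceeding `max_amplitude_mA`.
#' @param step_mA amplitude increment per step (mA), > 0; default 0.5.
#' @param rest_duration_s seconds of rest recording at the start of each step;
#'   default 60.
#' @param n_tap_blocks finger-tapping blocks per step (0 allowed for
#'   rest-only protocols); default 2.
#' @param tap_block_duration_s duration of one tapping block (s); default 10.
#' @param inter_block_rest_s rest between tapping blocks (s); default 10.
#' @param ramp_down_s linear ramp-down duration after the last stimulated
#'   step (s); default 23.
#' @param sampling_rate_hz LFP sampling rate (Hz); default 250.
#'
#' @return A `protocol_spec` list with the arguments above plus
#'   `step_amplitudes_mA`, the ordered amplitude sequence including the
#'   leading (OFF pre) and trailing (OFF post) 0.0 entries.
#' @seealso [protocol_schedule()] for the realised per-segment timing.
#' @export
make_protocol <- function(max_amplitude_mA, step_mA = 0.5,
                          rest_duration_s = 60, n_tap_blocks = 2,
                          tap_block_duration_s = 10, inter_block_rest_s = 10,
                          ramp_down_s = 23, sampling_rate_hz = 250) {
  if (!is.numeric(max_amplitude_mA) || length(max_amplitude_mA) != 1L ||
      !is.finite(max_amplitude_mA) || max_amplitude_mA <= 0)
    stop("invalid-argument: max_amplitude_mA must be a positive number")
  if (!is.numeric(step_mA) || length(step_mA) != 1L ||
      !is.finite(step_mA) || step_mA <= 0)
    stop("invalid-argument: step_mA must be a positive number")
  stopifnot(rest_duration_s > 0, tap_block_duration_s > 0,
            inter_block_rest_s > 0, ramp_down_s > 0, sampling_rate_hz > 0,
            n_tap_blocks >= 0, n_tap_blocks == round(n_tap_blocks))

  n_steps <- floor(max_amplitude_mA / step_mA + 1e-9)
  amps <- c(0, seq_len(n_steps) * step_mA, 0)

  structure(list(
    step_amplitudes_mA = amps,
    rest_duration_s = rest_duration_s,
    n_tap_blocks = as.integer(n_tap_blocks),
    tap_block_duration_s = tap_block_duration_s,
    inter_block_rest_s = inter_block_rest_s,
    ramp_down_s = ramp_down_s,
    sampling_rate_hz = sampling_rate_hz
  ), class = "protocol_spec")
}

#' Per-segment timing of a protocol
#'
#' Expands a [make_protocol()] specification into the realised event table:
#' one `stim_step:<mA>` annotation spanning each step, with nested `rest` and
#' `tap_block` annotations, and a `ramp_down` annotation between the last
#' stimulated step and the trailing OFF step. All intervals are half-open
#' `[onset, onset + duration)` in seconds from recording start.
#'
#' @param protocol a `protocol_spec`.
#' @return data.frame with columns `onset_s`, `duration_s`, `label`,
#'   `step_index` (1-based index into `step_amplitudes_mA`; NA for the ramp),
#'   and `step_mA`.
#' @export
protocol_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  p <- protocol
  n_amp <- length(p$step_amplitudes_mA)
  step_dur <- p$rest_duration_s + p$n_tap_blocks * p$tap_block_duration_s +
    max(p$n_tap_blocks - 1, 0) * p$inter_block_rest_s

  rows <- list()
  t0 <- 0
  for (i in seq_len(n_amp)) {
    amp <- p$step_amplitudes_mA[i]
    if (i == n_amp) { # ramp precedes the trailing OFF step
      rows[[length(rows) + 1L]] <- data.frame(
        onset_s = t0, duration_s = p$ramp_down_s, label = "ramp_down",
        step_index = NA_integer_, step_mA = NA_real_)
      t0 <- t0 + p$ramp_down_s
    }
    rows[[length(rows) + 1L]] <- data.frame(
      onset_s = t0, duration_s = step_dur,
      label = sprintf("stim_step:%g", amp),
      step_index = i, step_mA = amp)
    rows[[length(rows) + 1L]] <- data.frame(
      onset_s = t0, duration_s = p$rest_duration_s, label = "rest",
      step_index = i, step_mA = amp)
    tb <- t0 + p$rest_duration_s
    for (b in seq_len(p$n_tap_blocks)) {
      rows[[length(rows) + 1L]] <- data.frame(
        onset_s = tb, duration_s = p$tap_block_duration_s,
        label = "tap_block", step_index = i, step_mA = amp)
      tb <- tb + p$tap_block_duration_s + p$inter_block_rest_s
    }
    t0 <- t0 + step_dur
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Total duration (s) of a protocol
#' @param protocol a `protocol_spec`.
#' @return duration in seconds.
#' @export
protocol_duration <- function(protocol) {
  sched <- protocol_schedule(protocol)
  max(sched$onset_s + sched$duration_s)
}

#' Per-sample stimulation-amplitude trace for a protocol
#'
#' Constant within each step, linear during the ramp-down from the last
#' stimulated amplitude to 0 mA.
#'
#' @param protocol a `protocol_spec`.
#' @return numeric vector, one value per LFP sample.
#' @export
stim_trace <- function(protocol) {
  p <- protocol
  fs <- p$sampling_rate_hz
  sched <- protocol_schedule(p)
  n <- round(protocol_duration(p) * fs)
  t <- (seq_len(n) - 1) / fs
  out <- numeric(n)
  steps <- sched[grepl("^stim_step:", sched$label), ]
  for (i in seq_len(nrow(steps))) {
    idx <- t >= steps$onset_s[i] & t < steps$onset_s[i] + steps$duration_s[i]
    out[idx] <- steps$step_mA[i]
  }
  ramp <- sched[sched$label == "ramp_down", ]
  if (nrow(ramp) == 1L) {
    last_amp <- steps$step_mA[nrow(steps) - 1L] # step before trailing OFF
    idx <- t >= ramp$onset_s & t < ramp$onset_s + ramp$duration_s
    out[idx] <- last_amp * (1 - (t[idx] - ramp$onset_s) / ramp$duration_s)
  }
  out
}
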