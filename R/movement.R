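#' Movement-analysis configuration
#'
#' @param smooth_kernel_samples moving-average kernel applied to the
#'   rectified velocity; default 100 samples (0.4 s at 250 Hz).
#' @param drift_cutoff_hz lowpass cutoff (Hz) of the drift removed from the
#'   acceleration before integration; default 0.5.
#' @param z_axis_label channel label carrying the tapping axis.
#' @return a `movement_config` list.
#' @export
movement_config <- function(smooth_kernel_samples = 100,
                            drift_cutoff_hz = 0.5,
                            z_axis_label = "accel_z") {
  stopifnot(smooth_kernel_samples >= 1, drift_cutoff_hz > 0)
  structure(list(smooth_kernel_samples = as.integer(smooth_kernel_samples),
                 drift_cutoff_hz = drift_cutoff_hz,
                 z_axis_label = z_axis_label),
            class = "movement_config")
}

#' Tapping-velocity trace from z-axis acceleration
#'
#' Pipeline: remove sub-`drift_cutoff_hz` drift (zero-phase Butterworth
#' lowpass subtracted), numerically integrate acceleration to velocity
#' (cumulative sum x dt), rectify, smooth with a
#' `smooth_kernel_samples`-long moving average, and z-score over the entire
#' recording (denominator n-1). Z-scoring makes the trace comparable across
#' accelerometer hardware: any positive rescaling of the raw input leaves
#' the output unchanged.
#'
#' @param z_samples z-axis acceleration series.
#' @param fs sampling rate (Hz).
#' @param cfg a `movement_config`.
#' @param zscore set FALSE to return the smoothed rectified velocity in raw
#'   units (before z-scoring).
#' @return numeric velocity series, z-units (mean 0, SD 1) by default.
#' @export
velocity_trace <- function(z_samples, fs, cfg = movement_config(),
                           zscore = TRUE) {
  if (length(z_samples) < 10 * fs)
    stop("invalid-argument: need at least 10 s of accelerometer data")
  if (stats::sd(z_samples) == 0)
    stop("degenerate-input: constant accelerometer signal")
  lp <- signal::butter(2, cfg$drift_cutoff_hz / (fs / 2), "low")
  a <- z_samples - filtfilt_padded(lp, z_samples)
  v <- cumsum(a) / fs
  v <- v - filtfilt_padded(lp, v) # drift from integrated in-band noise
  v <- moving_average(abs(v), cfg$smooth_kernel_samples)
  if (!zscore) return(v)
  (v - mean(v)) / stats::sd(v)
}

#' Per-block and per-step tap velocities
#'
#' Averages the velocity trace inside each `tap_block` annotation, then
#' across the blocks of each stimulation step; relative values divide the
#' per-step means by the 0 mA pre-stimulation (baseline) step.
#'
#' @param velocity velocity series from [velocity_trace()].
#' @param events annotation data.frame (`onset_s`, `duration_s`, `label`)
#'   containing `tap_block` and `stim_step:<mA>` entries.
#' @param fs sampling rate of the velocity series (Hz).
#' @return a `velocity_summary`: `per_block` (data.frame step_index, step_mA,
#'   block, mean_velocity), `per_step` (data.frame step_index, step_mA,
#'   n_blocks, mean_velocity, relative_velocity).
#' @export
block_velocities <- function(velocity, events, fs) {
  steps <- session_steps(events)
  blocks <- events[events$label == "tap_block", , drop = FALSE]
  if (nrow(blocks) == 0)
    stop("invalid-argument: no tap_block annotations")
  n <- length(velocity)
  if (any(round((blocks$onset_s + blocks$duration_s) * fs) > n))
    stop("invalid-argument: tap_block annotation outside the velocity trace")
  step_of <- function(on) {
    hit <- which(steps$onset_s <= on + 1e-9 &
                   on < steps$onset_s + steps$duration_s - 1e-9)
    if (!length(hit)) NA_integer_ else hit[1]
  }
  per_block <- data.frame(
    step_index = vapply(blocks$onset_s, step_of, integer(1)),
    block = NA_integer_,
    mean_velocity = vapply(seq_len(nrow(blocks)), function(i) {
      idx <- seq.int(floor(blocks$onset_s[i] * fs) + 1L,
                     min(n, floor((blocks$onset_s[i] + blocks$duration_s[i]) * fs)))
      mean(velocity[idx])
    }, numeric(1)))
  if (anyNA(per_block$step_index))
    stop("invalid-argument: tap_block not contained in any stim_step")
  per_block$step_mA <- steps$step_mA[per_block$step_index]
  per_block$block <- stats::ave(per_block$step_index, per_block$step_index,
                                FUN = seq_along)
  agg <- stats::aggregate(mean_velocity ~ step_index, per_block, mean)
  per_step <- data.frame(step_index = agg$step_index,
                         step_mA = steps$step_mA[agg$step_index],
                         n_blocks = as.vector(table(per_block$step_index)),
                         mean_velocity = agg$mean_velocity)
  base <- per_step$mean_velocity[per_step$step_index == min(per_step$step_index) &
                                   per_step$step_mA == 0]
  if (length(base) != 1)
    stop("invalid-argument: missing 0 mA baseline step with tap blocks")
  per_step$relative_velocity <- per_step$mean_velocity / base
  structure(list(per_block = per_block[, c("step_index", "step_mA", "block",
                                           "mean_velocity")],
                 per_step = per_step),
            class = "velocity_summary")
}

#' Stimulation-step table of a session's events
#'
#' Reconstructs the ordered step table (onset, duration, amplitude) from the
#' `stim_step:<mA>` annotations; the leading 0 mA entry is the pre-DBS
#' baseline, a trailing 0 mA entry the post-DBS OFF step.
#'
#' @param events annotation data.frame or a `session_recording`.
#' @return data.frame `step_index`, `onset_s`, `duration_s`, `step_mA`.
#' @export
session_steps <- function(events) {
  if (inherits(events, "session_recording")) events <- events$events
  st <- events[grepl("^stim_step:", events$label), , drop = FALSE]
  if (nrow(st) == 0) stop("invalid-argument: no stim_step annotations")
  st <- st[order(st$onset_s), ]
  data.frame(step_index = seq_len(nrow(st)), onset_s = st$onset_s,
             duration_s = st$duration_s,
             step_mA = as.numeric(sub("^stim_step:", "", st$label)))
}
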