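#' Write a session recording to the session JSON dialect
#'
#' The on-disk format is a versioned JSON object (`schema_version` "1.0")
#' with fields `subject_id`, `hemisphere`, `sampling_rate_hz`, `channels`
#' (array of `{label, samples}` in uV), `stim_trace_mA`, `events` (array of
#' `{onset_s, duration_s, label}`) and `metadata`. Key order is fixed, so
#' two writes of the same recording are byte-identical. See
#' `inst/extdata/session.schema.json` for the schema.
#'
#' @param recording a `session_recording`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_session <- function(recording, path) {
  v <- validate_session(recording)
  if (!isTRUE(v)) stop("validation error: ", v)
  obj <- list(
    schema_version = "1.0",
    subject_id = recording$subject_id,
    hemisphere = recording$hemisphere,
    sampling_rate_hz = recording$sampling_rate_hz,
    channels = lapply(recording$channels, function(ch)
      list(label = ch$label, samples = ch$samples)),
    stim_trace_mA = recording$stim_trace_mA,
    events = lapply(seq_len(nrow(recording$events)), function(i)
      list(onset_s = recording$events$onset_s[i],
           duration_s = recording$events$duration_s[i],
           label = recording$events$label[i])),
    metadata = recording$metadata
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("io-error: cannot open ", path))
  on.exit(close(con))
  writeBin(charToRaw(as.character(json)), con)
  invisible(path)
}

#' Read a session recording from the session JSON dialect
#'
#' Validates the file against the published schema; violations raise a
#' `format-error` naming the failing field, and channel/stim length
#' mismatches raise a `corrupt-file` error. Round-trips with
#' [write_session()] up to floating-point representation.
#'
#' @param path file path.
#' @return a `session_recording`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("io-error: no such file: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  for (field in c("schema_version", "subject_id", "hemisphere",
                  "sampling_rate_hz", "channels", "stim_trace_mA", "events"))
    if (is.null(obj[[field]]))
      stop("format-error: missing field '", field, "'")
  if (!is.numeric(obj$sampling_rate_hz) || obj$sampling_rate_hz <= 0)
    stop("format-error: sampling_rate_hz")
  chans <- obj$channels
  if (is.data.frame(chans))
    chans <- lapply(seq_len(nrow(chans)), function(i)
      list(label = chans$label[i], samples = chans$samples[[i]]))
  if (length(chans) == 0) stop("format-error: channels empty")
  n <- length(chans[[1]]$samples)
  for (ch in chans) {
    if (is.null(ch$label) || is.null(ch$samples))
      stop("format-error: channels[].label/samples")
    if (length(ch$samples) != n || anyNA(ch$samples))
      stop("corrupt-file: channel '", ch$label,
           "' length/NaN mismatch")
  }
  if (length(obj$stim_trace_mA) != n)
    stop("corrupt-file: stim_trace_mA length != channel length")
  ev <- obj$events
  if (length(ev) == 0) {
    ev <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                     label = character(0))
  } else if (!is.data.frame(ev)) {
    stop("format-error: events")
  }
  rec <- structure(list(
    subject_id = obj$subject_id, hemisphere = obj$hemisphere,
    channels = chans, sampling_rate_hz = obj$sampling_rate_hz,
    stim_trace_mA = obj$stim_trace_mA,
    events = ev[, c("onset_s", "duration_s", "label")],
    metadata = if (is.null(obj$metadata)) list() else obj$metadata
  ), class = "session_recording")
  v <- validate_session(rec)
  if (!isTRUE(v)) stop("format-error: ", v)
  rec
}

# TRUE, or a string describing the first violated invariant
validate_session <- function(rec) {
  if (!inherits(rec, "session_recording")) return("not a session_recording")
  n <- length(rec$channels[[1]]$samples)
  for (ch in rec$channels) {
    if (length(ch$samples) != n) return("channel length mismatch")
    if (anyNA(ch$samples) || any(!is.finite(ch$samples)))
      return(paste0("non-finite samples in channel '", ch$label, "'"))
  }
  if (length(rec$stim_trace_mA) != n) return("stim_trace_mA length mismatch")
  if (rec$sampling_rate_hz <= 0) return("sampling_rate_hz must be > 0")
  dur <- n / rec$sampling_rate_hz
  ev <- rec$events
  if (nrow(ev) > 0) {
    if (any(ev$duration_s < 0)) return("negative event duration")
    if (any(ev$onset_s < 0 | ev$onset_s + ev$duration_s > dur + 1e-6))
      return("event outside [0, duration]")
    ok <- grepl("^(rest|tap_block|ramp_down|stim_step:[0-9.]+)$", ev$label)
    if (!all(ok)) return(paste0("unknown event label '", ev$label[!ok][1], "'"))
  }
  TRUE
}

#' Write / read an accelerometer trace as CSV
#'
#' Plain CSV with header `time_s,x,y,z`; the sampling rate is recovered from
#' the time column on read, and `time_s[1]` carries the accelerometer
#' clock's offset relative to the LFP clock.
#'
#' @param accel an `accel_trace`.
#' @param path file path.
#' @return invisibly `path` (write); an `accel_trace` (read).
#' @export
write_accel_csv <- function(accel, path) {
  stopifnot(inherits(accel, "accel_trace"))
  t <- accel$start_offset_s + (seq_along(accel$z) - 1) / accel$sampling_rate_hz
  dt <- data.table::data.table(time_s = t, x = accel$x, y = accel$y,
                               z = accel$z)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_accel_csv
#' @export
read_accel_csv <- function(path) {
  if (!file.exists(path)) stop("io-error: no such file: ", path)
  dt <- data.table::fread(path)
  need <- c("time_s", "x", "y", "z")
  if (!all(need %in% names(dt)))
    stop("format-error: accelerometer CSV needs columns time_s,x,y,z")
  fs <- 1 / stats::median(diff(dt$time_s))
  structure(list(sampling_rate_hz = fs, x = dt$x, y = dt$y, z = dt$z,
                 start_offset_s = dt$time_s[1], metadata = list()),
            class = "accel_trace")
}

#' Merge an accelerometer trace into an LFP session
#'
#' Resamples the accelerometer z-axis to the LFP rate (anti-alias Butterworth
#' lowpass before decimation, then linear interpolation at the LFP sample
#' times after applying `start_offset_s`), cuts it to the LFP duration, and
#' appends it as channel `"accel_z"`. Event annotations are untouched.
#'
#' @param recording a `session_recording`.
#' @param accel an `accel_trace` covering the LFP time span.
#' @return a new `session_recording` with the extra channel.
#' @export
merge_accelerometer <- function(recording, accel) {
  stopifnot(inherits(recording, "session_recording"),
            inherits(accel, "accel_trace"))
  fs_lfp <- recording$sampling_rate_hz
  n_lfp <- length(recording$channels[[1]]$samples)
  t_lfp <- (seq_len(n_lfp) - 1) / fs_lfp
  t_acc_end <- accel$start_offset_s + (length(accel$z) - 1) / accel$sampling_rate_hz
  if (accel$start_offset_s > 0 || t_acc_end < t_lfp[n_lfp] - 1e-9)
    stop("alignment-error: accelerometer does not cover the LFP time span")
  z <- accel$z
  if (accel$sampling_rate_hz > fs_lfp) {
    cutoff <- 0.4 * fs_lfp
    bf <- signal::butter(4, cutoff / (accel$sampling_rate_hz / 2), "low")
    z <- filtfilt_padded(bf, z)
  }
  z250 <- resample_at(z, accel$sampling_rate_hz, t_lfp, t0 = accel$start_offset_s)
  out <- recording
  out$channels[[length(out$channels) + 1L]] <-
    list(label = "accel_z", samples = z250)
  out
}
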