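#' Spectral analysis configuration
#'
#' @param freqs_hz analysis frequencies (Hz); default 3-97 in 1 Hz steps.
#' @param n_cycles Morlet wavelet cycles; default 8.
#' @param norm_ranges_hz list of frequency ranges whose summed power defines
#'   the "% total sum" normalization denominator; default (3-47, 53-97),
#'   excluding the line-noise notch.
#' @param rest_window_s seconds of rest averaged per stimulation step.
#' @param recovery_window_s seconds profiled after stimulation cessation.
#' @param edge_trim_s seconds discarded at segment edges to exclude wavelet
#'   edge effects (default 2 s, beyond the 8-cycle wavelet at 5 Hz).
#' @param decim time-axis decimation factor of the stored power map; power
#'   envelopes below the analysis band vary far slower than the raw rate, so
#'   averaging statistics are unaffected.
#' @return a `spectral_config` list.
#' @export
spectral_config <- function(freqs_hz = 3:97, n_cycles = 8,
                            norm_ranges_hz = list(c(3, 47), c(53, 97)),
                            rest_window_s = 30, recovery_window_s = 20,
                            edge_trim_s = 2, decim = 5L) {
  stopifnot(all(freqs_hz > 0), n_cycles > 0, rest_window_s > 0,
            edge_trim_s >= 0, decim >= 1)
  structure(list(freqs_hz = freqs_hz, n_cycles = n_cycles,
                 norm_ranges_hz = norm_ranges_hz,
                 rest_window_s = rest_window_s,
                 recovery_window_s = recovery_window_s,
                 edge_trim_s = edge_trim_s, decim = as.integer(decim)),
            class = "spectral_config")
}

#' Canonical frequency band definitions
#'
#' theta 5-8, alpha 8-12, low beta 13-20, high beta 20-35, total beta
#' 13-35 Hz. Band endpoints are integer bins, inclusive at both ends, so the
#' shared endpoints (8, 20 Hz) belong to both adjacent bands.
#'
#' @param name one of "theta", "alpha", "low_beta", "high_beta", "total_beta".
#' @return a `band_definition` list with `name`, `lo_hz`, `hi_hz`.
#' @export
band_definition <- function(name = c("theta", "alpha", "low_beta",
                                     "high_beta", "total_beta")) {
  name <- match.arg(name)
  edges <- list(theta = c(5, 8), alpha = c(8, 12), low_beta = c(13, 20),
                high_beta = c(20, 35), total_beta = c(13, 35))[[name]]
  structure(list(name = name, lo_hz = edges[1], hi_hz = edges[2]),
            class = "band_definition")
}

#' All canonical bands
#' @return named list of `band_definition`s.
#' @export
all_bands <- function() {
  nm <- c("theta", "alpha", "low_beta", "high_beta", "total_beta")
  stats::setNames(lapply(nm, band_definition), nm)
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves the series with complex Morlet wavelets (Gaussian-windowed
#' complex exponentials, `n_cycles` cycles, implemented as one-sided Gaussian
#' windows in the frequency domain). Power is scaled so a unit-amplitude
#' sinusoid at an analysis frequency yields its mean-square power 0.5.
#' `edge_trim_s` is removed from both ends of the time axis and the map is
#' decimated by `cfg$decim`.
#'
#' @param samples numeric series (uV), ideally already filtered.
#' @param fs sampling rate (Hz).
#' @param cfg a `spectral_config`.
#' @return a `tfr`: list with `power` (matrix frequency x time, uV^2),
#'   `freqs_hz`, `times_s`, `fs_map` (time-axis rate after decimation) and
#'   `normalized` (FALSE).
#' @export
morlet_tfr <- function(samples, fs, cfg = spectral_config()) {
  stopifnot(inherits(cfg, "spectral_config"))
  n <- length(samples)
  sigma_t_max <- cfg$n_cycles / (2 * pi * min(cfg$freqs_hz))
  if (n / fs <= 2 * cfg$edge_trim_s + 6 * sigma_t_max)
    stop("invalid-argument: segment too short for the longest wavelet plus edge trim")
  d <- cfg$decim
  m <- stats::nextn(n, c(2, 3, 5)) # composite FFT grid; zero-padded tail
  while (m %% d != 0) m <- stats::nextn(m + 1, c(2, 3, 5))
  M <- m %/% d
  X <- stats::fft(c(samples, numeric(m - n)))
  f <- fft_freqs(m, fs)
  trim <- round(cfg$edge_trim_s * fs)
  keep <- seq.int(trim + 1L, n - trim, by = d)
  L <- length(keep)
  pow <- matrix(0, nrow = length(cfg$freqs_hz), ncol = L)
  # The analytic-signal convolution is evaluated only at the decimated,
  # trimmed sample times: the wavelet's Gaussian frequency window is
  # truncated at 5 sigma, phase-shifted by the trim offset, folded modulo
  # m/decim (time-domain decimation = spectral aliasing, exact), and
  # inverted with the short FFT.
  for (i in seq_along(cfg$freqs_hz)) {
    f0 <- cfg$freqs_hz[i]
    sigma_t <- cfg$n_cycles / (2 * pi * f0)
    sigma_f <- 1 / (2 * pi * sigma_t)
    k <- which(f > 0 & abs(f - f0) <= 5 * sigma_f)
    H <- 2 * exp(-2 * pi^2 * sigma_t^2 * (f[k] - f0)^2)
    Y <- X[k] * H * exp(2i * pi * (k - 1) * trim / m)
    pos0 <- (k[1] - 1) %% M
    nch <- ceiling((pos0 + length(k)) / M) # contiguous support, whole chunks
    Ypad <- c(complex(pos0), Y, complex(nch * M - length(Y) - pos0))
    Yf <- rowSums(matrix(Ypad, nrow = M))
    z <- stats::fft(Yf, inverse = TRUE)[seq_len(L)] / m
    pow[i, ] <- (Re(z)^2 + Im(z)^2) / 2
  }
  structure(list(power = pow, freqs_hz = cfg$freqs_hz,
                 times_s = (keep - 1) / fs, fs_map = fs / cfg$decim,
                 normalized = FALSE),
            class = "tfr")
}

#' Normalize a time-frequency map to % of total sum
#'
#' Divides every time-frequency cell by one session-level denominator: the
#' sum, over the normalization-range bins, of time-averaged power, divided
#' by 100. After normalization the time-averaged power summed over those
#' bins is exactly 100, and the map is invariant to rescaling of the input.
#'
#' @param tfr a `tfr` from [morlet_tfr()].
#' @param cfg a `spectral_config`.
#' @return the normalized `tfr` (`normalized = TRUE`, units % of total sum).
#' @export
normalize_total_sum <- function(tfr, cfg = spectral_config()) {
  stopifnot(inherits(tfr, "tfr"))
  sel <- norm_range_bins(tfr$freqs_hz, cfg)
  denom <- sum(rowMeans(tfr$power)[sel]) / 100
  if (!is.finite(denom) || denom <= 0)
    stop("degenerate-input: zero total power in normalization ranges")
  out <- tfr
  out$power <- tfr$power / denom
  out$normalized <- TRUE
  out$norm_denominator <- denom
  out
}

norm_range_bins <- function(freqs, cfg) {
  sel <- rep(FALSE, length(freqs))
  for (r in cfg$norm_ranges_hz) sel <- sel | (freqs >= r[1] & freqs <= r[2])
  sel
}

#' Time-averaged spectrum of a (normalized) map
#'
#' @param tfr a normalized `tfr`.
#' @param t_range optional `c(start, end)` seconds restricting the average.
#' @return a `normalized_spectrum`: `power_pct`, `freqs_hz`.
#' @export
spectrum_of <- function(tfr, t_range = NULL) {
  stopifnot(inherits(tfr, "tfr"))
  cols <- if (is.null(t_range)) seq_along(tfr$times_s) else
    which(tfr$times_s >= t_range[1] & tfr$times_s < t_range[2])
  if (!length(cols)) stop("invalid-argument: empty time range")
  structure(list(power_pct = rowMeans(tfr$power[, cols, drop = FALSE]),
                 freqs_hz = tfr$freqs_hz),
            class = "normalized_spectrum")
}

#' Periodogram-based normalized spectrum
#'
#' Smoothed periodogram (Daniell window, ~1 Hz bandwidth) binned onto the
#' integer analysis grid and normalized to % of total sum over the
#' normalization ranges. Unlike the Morlet map — whose bandwidth grows with
#' frequency (f / n_cycles) — this keeps ~1 Hz resolution across the whole
#' range, which the aliasing screen needs to resolve narrow tones above
#' 70 Hz.
#'
#' @param samples numeric series (uV).
#' @param fs sampling rate (Hz).
#' @param cfg a `spectral_config`.
#' @return a `normalized_spectrum`.
#' @export
periodogram_spectrum <- function(samples, fs, cfg = spectral_config()) {
  n <- length(samples)
  span <- max(3, round(1 * n / fs)) # ~1 Hz smoothing bandwidth
  pg <- stats::spec.pgram(stats::ts(samples, frequency = fs), spans = span,
                          taper = 0.1, plot = FALSE, detrend = TRUE)
  p <- vapply(cfg$freqs_hz, function(f0) {
    sel <- pg$freq >= f0 - 0.5 & pg$freq < f0 + 0.5
    mean(pg$spec[sel])
  }, numeric(1))
  sel <- norm_range_bins(cfg$freqs_hz, cfg)
  denom <- sum(p[sel]) / 100
  if (!is.finite(denom) || denom <= 0)
    stop("degenerate-input: zero total power in normalization ranges")
  structure(list(power_pct = p / denom, freqs_hz = cfg$freqs_hz),
            class = "normalized_spectrum")
}

#' Resting-state spectrum of one stimulation step
#'
#' Averages the normalized map over the first `rest_window_s` seconds of the
#' rest interval after trimming `edge_trim_s` from both interval edges. If
#' the trimmed interval is shorter than the window the full available length
#' is used and recorded; below 10 s the interval is rejected.
#'
#' @param tfr_norm a normalized `tfr`.
#' @param rest_interval either a one-row data.frame with `onset_s` and
#'   `duration_s` (an annotation) or a numeric `c(onset, duration)`.
#' @param cfg a `spectral_config`.
#' @return a `normalized_spectrum` with attribute `actual_window_s`.
#' @export
rest_spectrum <- function(tfr_norm, rest_interval, cfg = spectral_config()) {
  if (is.data.frame(rest_interval))
    rest_interval <- c(rest_interval$onset_s[1], rest_interval$duration_s[1])
  onset <- rest_interval[1] + cfg$edge_trim_s
  avail <- rest_interval[2] - 2 * cfg$edge_trim_s
  if (avail < 10)
    stop("invalid-argument: trimmed rest interval below 10 s")
  win <- min(cfg$rest_window_s, avail)
  sp <- spectrum_of(tfr_norm, c(onset, onset + win))
  attr(sp, "actual_window_s") <- win
  sp
}

#' Mean band power of a normalized spectrum
#'
#' Mean of `power_pct` over the integer frequency bins from `lo_hz` to
#' `hi_hz` inclusive.
#'
#' @param spectrum a `normalized_spectrum`.
#' @param band a `band_definition`.
#' @return scalar, % of total sum per Hz.
#' @export
band_power <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "normalized_spectrum"),
            inherits(band, "band_definition"))
  sel <- spectrum$freqs_hz >= band$lo_hz & spectrum$freqs_hz <= band$hi_hz
  if (!any(sel) || min(spectrum$freqs_hz) > band$lo_hz ||
      max(spectrum$freqs_hz) < band$hi_hz)
    stop("invalid-argument: band outside spectrum coverage")
  mean(spectrum$power_pct[sel])
}

#' Detect the spectral peak in a search band
#'
#' Fits a log-log linear aperiodic baseline to the spectrum (iteratively
#' re-fit on the sub-baseline points so oscillatory bumps do not bias the
#' fit), then returns the highest local maximum of the spectrum within the
#' search band that exceeds the baseline by at least `prominence`
#' (% total sum per Hz). Equal-height candidates resolve to the lower
#' frequency.
#'
#' @param spectrum a `normalized_spectrum`.
#' @param search_lo,search_hi search band (Hz); defaults 8-35.
#' @param prominence required excess over the aperiodic fit; default 0.5.
#' @return a `peak_estimate`: `freq_hz`, `amplitude_pct`, `found`.
#' @export
detect_beta_peak <- function(spectrum, search_lo = 8, search_hi = 35,
                             prominence = 0.5) {
  stopifnot(inherits(spectrum, "normalized_spectrum"))
  f <- spectrum$freqs_hz
  if (min(f) > search_lo || max(f) < search_hi)
    stop("invalid-argument: spectrum does not cover the search band")
  p <- pmax(spectrum$power_pct, 1e-12)
  lf <- log(f); lp <- log(p)
  keep <- rep(TRUE, length(f))
  for (iter in 1:3) {
    fit <- stats::lm.fit(cbind(1, lf[keep]), lp[keep])
    pred <- fit$coefficients[1] + fit$coefficients[2] * lf
    keep <- (lp - pred) <= 0.1
    if (sum(keep) < 5) break
  }
  baseline <- exp(pred)
  idx <- which(f >= search_lo & f <= search_hi)
  inner <- idx[idx > 1 & idx < length(f)]
  is_max <- vapply(inner, function(i) p[i] > p[i - 1] && p[i] >= p[i + 1],
                   logical(1))
  cand <- inner[is_max & (p[inner] - baseline[inner]) >= prominence]
  if (!length(cand))
    return(structure(list(freq_hz = NA_real_, amplitude_pct = NA_real_,
                          found = FALSE), class = "peak_estimate"))
  best <- cand[order(-p[cand], f[cand])][1] # ties -> lower frequency
  structure(list(freq_hz = f[best], amplitude_pct = spectrum$power_pct[best],
                 found = TRUE), class = "peak_estimate")
}

#' Post-cessation baseline recovery of low-beta power
#'
#' For each of the `recovery_window_s` (20) one-second windows after
#' stimulation cessation, the mean low-beta (13-20 Hz) power of the
#' normalized map is divided by the pre-stimulation baseline's low-beta
#' power. The recovery time is where that ratio reaches `threshold` (0.8).
#' One-second band-power estimates of a bursting (~3 Hz bandwidth)
#' oscillation carry large sampling noise (few effective degrees of
#' freedom), so the default estimator fits the exponential return
#' `ratio(t) = c1 - c2 * exp(-t / tau)` to the 20-point profile by least
#' squares (grid over tau, linear in c1/c2) and reads the threshold
#' crossing off the fitted curve; `method = "threshold"` instead returns
#' the raw rule — the start of the first window whose ratio reaches the
#' threshold sustained for two consecutive seconds. Profiles that never
#' reach the threshold (fitted asymptote below it, or no sustained
#' crossing) are flagged unrecovered.
#'
#' @param tfr_norm a normalized `tfr` covering at least
#'   `cessation_time_s + recovery_window_s`.
#' @param cessation_time_s time stimulation reached 0 mA (s).
#' @param baseline a `normalized_spectrum` from the pre-stimulation rest.
#' @param cfg a `spectral_config`.
#' @param threshold recovery ratio; default 0.8.
#' @param method "fit" (default) or "threshold"; see Details.
#' @return a `recovery_profile`: `rel_low_beta` (length 20), `recovery_time_s`
#'   (NA when unrecovered), `recovered`, `method`.
#' @export
baseline_recovery <- function(tfr_norm, cessation_time_s, baseline,
                              cfg = spectral_config(), threshold = 0.8,
                              method = c("fit", "threshold")) {
  stopifnot(inherits(tfr_norm, "tfr"), inherits(baseline, "normalized_spectrum"))
  method <- match.arg(method)
  nwin <- cfg$recovery_window_s
  if (max(tfr_norm$times_s) < cessation_time_s + nwin)
    stop("invalid-argument: need ", nwin, " s of data after cessation")
  lb <- band_definition("low_beta")
  base_lb <- band_power(baseline, lb)
  rel <- vapply(seq_len(nwin) - 1, function(s) {
    sp <- spectrum_of(tfr_norm, cessation_time_s + c(s, s + 1))
    band_power(sp, lb) / base_lb
  }, numeric(1))
  rec_t <- if (method == "threshold") {
    ok <- rel >= threshold
    sustained <- which(ok[-length(ok)] & ok[-1])
    if (length(sustained)) sustained[1] - 1 else NA_real_
  } else {
    recovery_fit_crossing(rel, threshold)
  }
  structure(list(rel_low_beta = rel, recovery_time_s = rec_t,
                 recovered = !is.na(rec_t), method = method),
            class = "recovery_profile")
}

# least-squares exponential-return fit of a per-second recovery profile;
# returns the fitted threshold-crossing time (s) or NA if the asymptote
# stays below the threshold
recovery_fit_crossing <- function(rel, threshold) {
  t <- seq_along(rel) - 0.5 # window centres
  best <- NULL
  for (tau in seq(1, 40, by = 0.25)) {
    fit <- stats::lm.fit(cbind(1, exp(-t / tau)), rel)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, tau = tau, c1 = fit$coefficients[1],
                   c2 = -fit$coefficients[2])
  }
  if (best$c2 <= 0) # profile not rising: already at (or past) asymptote
    return(if (mean(rel) >= threshold) 0 else NA_real_)
  if (best$c1 <= threshold) return(NA_real_) # never reaches threshold
  tc <- best$tau * log(best$c2 / (best$c1 - threshold))
  max(0, tc)
}
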