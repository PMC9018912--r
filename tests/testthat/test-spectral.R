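test_that("the wavelet map localizes pure and mixed oscillations", {
  fs <- 250
  t <- (0:(30 * fs - 1)) / fs
  cfg <- spectral_config()
  tf <- morlet_tfr(sin(2 * pi * 20 * t), fs, cfg)
  avg <- rowMeans(tf$power)
  expect_equal(tf$freqs_hz[which.max(avg)], 20)
  # unit sinusoid: mean-square power 0.5 at its own bin (Parseval-style
  # scaling, constant factor 1 by construction) across the analysis range
  for (f0 in c(5, 10, 20, 30, 40)) {
    tfp <- morlet_tfr(sin(2 * pi * f0 * t), fs, cfg)
    expect_equal(mean(tfp$power[tfp$freqs_hz == f0, ]), 0.5,
                 tolerance = 0.02)
  }
  # equal-amplitude mixture: local maxima at both components
  tfm <- morlet_tfr(sin(2 * pi * 10 * t) + sin(2 * pi * 25 * t), fs, cfg)
  avg <- rowMeans(tfm$power)
  loc <- which(diff(sign(diff(avg))) == -2) + 1
  expect_true(10 %in% tfm$freqs_hz[loc])
  expect_true(25 %in% tfm$freqs_hz[loc])
  # zero input: all-zero map, which the normalizer refuses
  tf0 <- morlet_tfr(numeric(30 * fs), fs, cfg)
  expect_true(all(tf0$power == 0))
  expect_error(normalize_total_sum(tf0, cfg), "degenerate-input")
  expect_error(morlet_tfr(rnorm(100), fs, cfg), "invalid-argument")
})

test_that("normalization conserves 100% over the reference ranges and is
           scale invariant", {
  tfrn <- default_tfrn()
  cfg <- spectral_config()
  sel <- betadose:::norm_range_bins(tfrn$freqs_hz, cfg)
  expect_equal(sum(rowMeans(tfrn$power)[sel]), 100, tolerance = 1e-6)
  # rescaling the input leaves the normalized map unchanged
  d <- default_session()
  x <- filter_session(d$session)$channels[[1]]$samples
  short <- x[1:(30 * 250)]
  n1 <- normalize_total_sum(morlet_tfr(short, 250, cfg), cfg)
  n2 <- normalize_total_sum(morlet_tfr(short * 10, 250, cfg), cfg)
  expect_equal(n1$power, n2$power, tolerance = 1e-9)
})

test_that("rest spectra average the configured window within one step", {
  tfrn <- default_tfrn()
  d <- default_session()
  rests <- d$session$events[d$session$events$label == "rest", ]
  sp <- rest_spectrum(tfrn, rests[1, ])
  expect_equal(attr(sp, "actual_window_s"), 30)
  # equals the map's own time average over that window
  direct <- spectrum_of(tfrn, c(rests$onset_s[1] + 2, rests$onset_s[1] + 32))
  expect_equal(sp$power_pct, direct$power_pct, tolerance = 1e-9)
  # a short interval falls back to the available length, recorded
  sp2 <- rest_spectrum(tfrn, c(rests$onset_s[1], 20))
  expect_equal(attr(sp2, "actual_window_s"), 16)
  expect_error(rest_spectrum(tfrn, c(rests$onset_s[1], 12)),
               "invalid-argument")
  # two disjoint windows of one stationary stretch agree within sampling error
  sp_a <- spectrum_of(tfrn, c(2, 30))
  sp_b <- spectrum_of(tfrn, c(30, 58))
  lb <- band_definition("low_beta")
  expect_equal(band_power(sp_a, lb) / band_power(sp_b, lb), 1,
               tolerance = 0.35)
})

test_that("band power averages inclusive integer bins", {
  f <- 3:97
  flat <- structure(list(power_pct = rep(1, length(f)), freqs_hz = f),
                    class = "normalized_spectrum")
  for (bn in c("theta", "alpha", "low_beta", "high_beta", "total_beta"))
    expect_equal(band_power(flat, band_definition(bn)), 1)
  conc <- flat
  conc$power_pct[f == 16] <- 50
  expect_gt(band_power(conc, band_definition("low_beta")),
            band_power(conc, band_definition("high_beta")))
  # shared endpoint 20 Hz belongs to both beta sub-bands
  edge <- flat; edge$power_pct[f == 20] <- 9
  expect_equal(band_power(edge, band_definition("low_beta")), (7 + 9) / 8)
  expect_equal(band_power(edge, band_definition("high_beta")), (15 + 9) / 16)
  lowcov <- structure(list(power_pct = rep(1, 5), freqs_hz = 10:14),
                      class = "normalized_spectrum")
  expect_error(band_power(lowcov, band_definition("low_beta")),
               "invalid-argument")
})

test_that("peak detection finds bumps above the aperiodic fit", {
  f <- 3:97
  base <- 40 * f^-1.2
  bump <- function(f0, h, w = 2) h * exp(-(f - f0)^2 / (2 * w^2))
  mk <- function(p) structure(list(power_pct = p, freqs_hz = f),
                              class = "normalized_spectrum")
  pk <- detect_beta_peak(mk(base + bump(16, 5)))
  expect_true(pk$found)
  expect_equal(pk$freq_hz, 16, tolerance = 1)
  # monotone aperiodic spectrum: nothing to find
  expect_false(detect_beta_peak(mk(base))$found)
  # two bumps: the higher one wins even at higher frequency
  pk2 <- detect_beta_peak(mk(base + bump(14, 3) + bump(25, 6)))
  expect_equal(pk2$freq_hz, 25, tolerance = 1)
  # exact ties resolve to the lower frequency
  p3 <- base * 0 + 1
  p3[f == 15] <- 4; p3[f == 28] <- 4
  expect_equal(detect_beta_peak(mk(p3))$freq_hz, 15)
  lowcov <- structure(list(power_pct = base[1:20], freqs_hz = f[1:20]),
                      class = "normalized_spectrum")
  expect_error(detect_beta_peak(lowcov), "invalid-argument")
})

test_that("injected beta peaks are recovered within 1 Hz on full sessions", {
  hits <- 0; n_seeds <- 10
  p <- short_protocol(rest = 22, max_mA = 0.5)
  for (sd_ in seq_len(n_seeds)) {
    peak <- sample(12:19, 1)
    tr <- ground_truth(beta_peak_hz = peak)
    s <- simulate_lfp(p, tr, seed = 1100 + sd_)
    x <- filter_session(s)$channels[[1]]$samples
    tfrn <- normalize_total_sum(morlet_tfr(x, 250))
    rests <- s$events[s$events$label == "rest", ]
    pk <- detect_beta_peak(rest_spectrum(tfrn, rests[1, ]))
    hits <- hits + (pk$found && abs(pk$freq_hz - peak) <= 1)
  }
  expect_gte(hits, n_seeds - 1)
})

test_that("baseline recovery profiles behave at the extremes", {
  cfg <- spectral_config()
  # stationary map: post stretch is its own baseline, recovery immediate
  d <- default_session()
  x <- filter_session(d$session)$channels[[1]]$samples[1:(60 * 250)]
  tfrn <- normalize_total_sum(morlet_tfr(x, 250, cfg), cfg)
  base <- spectrum_of(tfrn, c(2, 32))
  rec <- baseline_recovery(tfrn, 32, base, cfg)
  expect_true(rec$recovered)
  expect_lte(rec$recovery_time_s, 1)
  # suppression held: never recovers
  tr <- ground_truth(recovery_tau_s = 1e6)
  p <- make_protocol(2.5, rest_duration_s = 26, n_tap_blocks = 0)
  s <- simulate_lfp(p, tr, seed = 7)
  tfrn2 <- normalize_total_sum(morlet_tfr(
    filter_session(s)$channels[[1]]$samples, 250, cfg), cfg)
  rests <- s$events[s$events$label == "rest", ]
  ramp <- s$events[s$events$label == "ramp_down", ]
  rec2 <- baseline_recovery(tfrn2, ramp$onset_s + ramp$duration_s,
                            rest_spectrum(tfrn2, rests[1, ], cfg), cfg)
  expect_false(rec2$recovered)
  expect_true(all(rec2$rel_low_beta < 0.5))
  expect_error(baseline_recovery(tfrn, 50, base, cfg), "invalid-argument")
})

test_that("low-beta step means decrease monotonically under suppression", {
  ok <- 0; n_seeds <- 6
  p <- short_protocol()
  lb <- band_definition("low_beta")
  for (sd_ in seq_len(n_seeds)) {
    s <- simulate_lfp(p, ground_truth(), seed = 1200 + sd_)
    tfrn <- normalize_total_sum(morlet_tfr(
      filter_session(s)$channels[[1]]$samples, 250))
    rests <- s$events[s$events$label == "rest", ]
    pw <- vapply(1:6, function(i)
      band_power(rest_spectrum(tfrn, rests[i, ]), lb), numeric(1))
    ok <- ok + (cor(pw, 1:6, method = "spearman") == -1)
  }
  expect_equal(ok, n_seeds)
})
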