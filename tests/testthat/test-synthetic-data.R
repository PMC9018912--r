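test_that("simulation is bit-identical for a fixed seed", {
  p <- tiny_protocol()
  tr <- ground_truth()
  s1 <- simulate_lfp(p, tr, seed = 11)
  s2 <- simulate_lfp(p, tr, seed = 11)
  expect_identical(s1$channels[[1]]$samples, s2$channels[[1]]$samples)
  a1 <- simulate_accelerometer(p, tr, seed = 12)
  a2 <- simulate_accelerometer(p, tr, seed = 12)
  expect_identical(a1$z, a2$z)
  s3 <- simulate_lfp(p, tr, seed = 13)
  expect_false(identical(s1$channels[[1]]$samples, s3$channels[[1]]$samples))
})

test_that("seeded simulation restores the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_lfp(tiny_protocol(), ground_truth(), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("without suppression, beta power is flat across steps", {
  p <- short_protocol(rest = 22)
  tr <- ground_truth(suppression_k = 0)
  s <- simulate_lfp(p, tr, seed = 21)
  f <- filter_session(s)
  tfrn <- normalize_total_sum(morlet_tfr(f$channels[[1]]$samples, 250))
  rests <- s$events[s$events$label == "rest", ]
  lb <- band_definition("low_beta")
  pw <- vapply(seq_len(nrow(rests)), function(i)
    band_power(rest_spectrum(tfrn, rests[i, ]), lb), numeric(1))
  expect_lt(max(pw) / min(pw), 2) # sampling scatter only, no trend
  expect_gt(cor.test(pw[1:6], 1:6)$p.value, 0.05)
})

test_that("log beta power declines with amplitude at slope -2k", {
  # long-ish rest windows so per-step estimates are tight
  p <- make_protocol(2.5, rest_duration_s = 34, n_tap_blocks = 0)
  tr <- ground_truth(suppression_k = 1.0)
  s <- simulate_lfp(p, tr, seed = 22)
  f <- filter_session(s)
  tfrn <- normalize_total_sum(morlet_tfr(f$channels[[1]]$samples, 250))
  rests <- s$events[s$events$label == "rest", ]
  lb <- band_definition("low_beta")
  pw <- vapply(1:6, function(i)
    band_power(rest_spectrum(tfrn, rests[i, ]), lb), numeric(1))
  amps <- p$step_amplitudes_mA[1:6]
  slope <- coef(lm(log(pw) ~ amps))[2]
  expect_equal(unname(slope), -2, tolerance = 0.2) # within 10% of -2k
})

test_that("with oscillators silenced the background follows the 1/f exponent", {
  for (chi in c(1.0, 1.6)) {
    tr <- ground_truth(beta_amp0 = 0, theta_amp = 0, alpha_amp = 0,
                       line_noise_amp = 0, noise_sd = 0, suppression_k = 0,
                       aperiodic_exponent = chi)
    p <- make_protocol(0.5, rest_duration_s = 60, n_tap_blocks = 0,
                       ramp_down_s = 5)
    s <- simulate_lfp(p, tr, seed = 31)
    sp <- spec.pgram(ts(s$channels[[1]]$samples, frequency = 250),
                     spans = 15, taper = 0, plot = FALSE)
    sel <- sp$freq >= 5 & sp$freq <= 45
    est <- -coef(lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2]
    expect_equal(unname(est), chi, tolerance = 0.2 / chi) # +-0.2 absolute
  }
})

test_that("tap velocity couples to beta suppression as specified", {
  p <- short_protocol(blocks = 2)
  # no coupling: block velocities equal across steps within noise
  tr0 <- ground_truth(velocity_coupling_c = 0)
  a0 <- simulate_accelerometer(p, tr0, seed = 41)
  v0 <- a0$metadata$blocks$true_velocity
  expect_lt(diff(range(v0)), 6 * tr0$vel_noise_sd)
  # positive coupling with suppression: monotone increase in expectation
  tr1 <- ground_truth(velocity_coupling_c = 1.4, vel_noise_sd = 0)
  a1 <- simulate_accelerometer(p, tr1, seed = 42)
  per_step <- tapply(a1$metadata$blocks$true_velocity,
                     a1$metadata$blocks$step_index, mean)
  expect_true(all(diff(per_step[1:6]) > 0))
  # closed form at step I: v0 * (1 + c * (1 - exp(-k I)))
  expect_equal(unname(per_step[["6"]]),
               1 * (1 + 1.4 * (1 - exp(-tr1$suppression_k * 2.5))),
               tolerance = 1e-6)
})

test_that("outside tap blocks the z-axis is pure noise at noise_sd", {
  p <- short_protocol(blocks = 2)
  tr <- ground_truth()
  a <- simulate_accelerometer(p, tr, seed = 51)
  sched <- protocol_schedule(p)
  blocks <- sched[sched$label == "tap_block", ]
  t <- (seq_along(a$z) - 1) / a$sampling_rate_hz
  inside <- rep(FALSE, length(t))
  for (i in seq_len(nrow(blocks)))
    inside <- inside | (t >= blocks$onset_s[i] - 0.1 &
                          t < blocks$onset_s[i] + blocks$duration_s[i] + 0.1)
  expect_equal(sd(a$z[!inside]), tr$noise_sd, tolerance = 0.02)
})

test_that("ECG injection adds a periodic artifact and is detectable", {
  p <- short_protocol(rest = 22)
  tr <- ground_truth()
  s <- simulate_lfp(p, tr, seed = 61)
  expect_identical(inject_ecg_artifact(s, 60, 0), s) # amp 0 is identity
  expect_error(inject_ecg_artifact(s, 20, 1), "invalid-argument")
  expect_error(inject_ecg_artifact(s, 200, 1), "invalid-argument")
  rms <- sd(s$channels[[1]]$samples)
  s60 <- inject_ecg_artifact(s, 60, 3 * rms)
  # original untouched
  expect_false(identical(s60$channels[[1]]$samples, s$channels[[1]]$samples))
  # autocorrelation of the artifact-bearing signal peaks at lag 1.0 s
  x <- s60$channels[[1]]$samples
  ac <- acf(abs(x - mean(x)), lag.max = 300, plot = FALSE)$acf[, 1, 1]
  lag_peak <- (which.max(ac[200:300]) + 198) / 250
  expect_equal(lag_peak, 1.0, tolerance = 0.05)
})

test_that("generated sessions carry a valid schedule and stim trace", {
  d <- default_session()
  s <- d$session
  expect_equal(length(s$stim_trace_mA), length(s$channels[[1]]$samples))
  expect_true(all(s$stim_trace_mA >= 0))
  expect_equal(max(s$stim_trace_mA), 2.5)
  expect_true(isTRUE(betadose:::validate_session(s)))
})
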