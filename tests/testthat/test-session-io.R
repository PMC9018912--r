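test_that("sessions round-trip through the JSON dialect", {
  p <- tiny_protocol()
  s <- simulate_lfp(p, ground_truth(), seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_session(s, path)
  s2 <- read_session(path)
  expect_equal(s2$channels[[1]]$samples, s$channels[[1]]$samples)
  expect_equal(s2$stim_trace_mA, s$stim_trace_mA)
  expect_equal(s2$events$label, s$events$label)
  expect_equal(s2$events$onset_s, s$events$onset_s)
  expect_equal(s2$subject_id, s$subject_id)
  expect_equal(s2$sampling_rate_hz, s$sampling_rate_hz)
})

test_that("two writes of the same recording are byte-identical", {
  s <- simulate_lfp(tiny_protocol(), ground_truth(), seed = 2)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_session(s, p1); write_session(s, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("schema violations are reported by field", {
  s <- simulate_lfp(tiny_protocol(), ground_truth(), seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_session(s, path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  # missing stimulation trace
  bad <- obj; bad$stim_trace_mA <- NULL
  pb <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, pb, auto_unbox = TRUE, digits = NA)
  expect_error(read_session(pb), "stim_trace_mA")
  # truncated channel array
  bad2 <- obj
  bad2$channels$samples[[1]] <- bad2$channels$samples[[1]][-(1:10)]
  pb2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad2, pb2, auto_unbox = TRUE, digits = NA)
  expect_error(read_session(pb2), "corrupt-file")
  expect_error(read_session("no/such/file.json"), "io-error")
})

test_that("NaN samples are refused at write time", {
  s <- simulate_lfp(tiny_protocol(), ground_truth(), seed = 4)
  s$channels[[1]]$samples[5] <- NaN
  expect_error(write_session(s, withr::local_tempfile()), "non-finite")
})

test_that("an empty events table is written and read back", {
  s <- simulate_lfp(tiny_protocol(), ground_truth(), seed = 5)
  s$events <- s$events[0, ]
  path <- withr::local_tempfile(fileext = ".json")
  write_session(s, path)
  expect_equal(nrow(read_session(path)$events), 0)
})

test_that("accelerometer CSV round-trips with rate and offset", {
  a <- simulate_accelerometer(tiny_protocol(), ground_truth(), seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_accel_csv(a, path)
  a2 <- read_accel_csv(path)
  expect_equal(a2$sampling_rate_hz, a$sampling_rate_hz, tolerance = 1e-9)
  expect_equal(a2$z, a$z, tolerance = 1e-12)
  expect_equal(a2$start_offset_s, 0)
})

test_that("merging resamples the z-axis to the LFP clock", {
  p <- tiny_protocol()
  s <- simulate_lfp(p, ground_truth(), seed = 7)
  fs <- s$sampling_rate_hz
  n <- length(s$channels[[1]]$samples)
  dur <- n / fs
  # accel at 1000 Hz carrying a pure 5 Hz sinusoid: amplitude preserved
  t1k <- seq(0, dur + 0.5, by = 1 / 1000)
  acc <- structure(list(sampling_rate_hz = 1000, x = 0 * t1k, y = 0 * t1k,
                        z = sin(2 * pi * 5 * t1k), start_offset_s = 0,
                        metadata = list()), class = "accel_trace")
  m <- merge_accelerometer(s, acc)
  z <- m$channels[[length(m$channels)]]$samples
  expect_equal(m$channels[[length(m$channels)]]$label, "accel_z")
  expect_equal(length(z), n)
  mid <- z[round(n / 3):round(2 * n / 3)]
  expect_equal(max(abs(mid)), 1, tolerance = 0.02)
  # events untouched by merging
  expect_identical(m$events, s$events)
  # accel already at 250 Hz, zero offset: appended unchanged up to truncation
  t250 <- seq(0, dur + 0.5, by = 1 / 250)
  acc250 <- structure(list(sampling_rate_hz = 250, x = 0 * t250, y = 0 * t250,
                           z = cos(2 * pi * 3 * t250), start_offset_s = 0,
                           metadata = list()), class = "accel_trace")
  m2 <- merge_accelerometer(s, acc250)
  expect_equal(m2$channels[[length(m2$channels)]]$samples,
               acc250$z[seq_len(n)], tolerance = 1e-9)
  # insufficient coverage
  accshort <- acc250
  accshort$z <- accshort$z[seq_len(round(n / 2))]
  expect_error(merge_accelerometer(s, accshort), "alignment-error")
})
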