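# Shared small fixtures. Short protocols keep runtimes down; rest windows
# stay >= the 10 s minimum after 2 s edge trims.

short_protocol <- function(rest = 14, blocks = 0, ramp = 5, max_mA = 2.5)
  make_protocol(max_mA, rest_duration_s = rest, n_tap_blocks = blocks,
                ramp_down_s = ramp)

# a rest-only single-step protocol: 2 x rest + ramp seconds long
tiny_protocol <- function(rest = 14, ramp = 3)
  make_protocol(0.5, rest_duration_s = rest, n_tap_blocks = 0,
                ramp_down_s = ramp)

# cache for objects reused across test files within one run
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# one default full-protocol session + accelerometer, reused widely
default_session <- function() cached("default_session", {
  p <- make_protocol(2.5)
  tr <- ground_truth()
  list(protocol = p, truth = tr,
       session = simulate_lfp(p, tr, seed = 42),
       accel = simulate_accelerometer(p, tr, seed = 43))
})

# its filtered, normalized time-frequency map
default_tfrn <- function() cached("default_tfrn", {
  d <- default_session()
  f <- filter_session(d$session)
  normalize_total_sum(morlet_tfr(f$channels[[1]]$samples,
                                 d$session$sampling_rate_hz))
})
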