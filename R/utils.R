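#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded simulation calls
#' do not perturb the global RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# moving average with edge-shortened windows (centred, width k samples)
moving_average <- function(x, k) {
  stopifnot(k >= 1)
  if (k == 1) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- floor(k / 2)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (k - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# linear interpolation resample of x sampled at fs_in onto times t_out (s)
resample_at <- function(x, fs_in, t_out, t0 = 0) {
  t_in <- t0 + (seq_along(x) - 1) / fs_in
  stats::approx(t_in, x, xout = t_out, rule = 1)$y
}
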