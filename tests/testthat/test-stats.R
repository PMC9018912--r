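test_that("the paired permutation test matches exact enumeration", {
  # identical pairs: p = 1 exactly
  x <- c(1, 2, 3, 4, 5)
  r <- paired_permutation_test(x, x)
  expect_equal(r$p_value, 1.0)
  expect_true(r$exhaustive)
  # n = 10, all differences equal and same-signed: only the two extreme
  # sign patterns reach the observed statistic
  r2 <- paired_permutation_test(rep(1, 10), rep(0, 10))
  expect_true(r2$exhaustive)
  expect_equal(r2$n_used, 1024)
  expect_equal(r2$p_value, 2 / 1024)
  # p respects its attainable floor
  set.seed(4)
  r3 <- paired_permutation_test(rnorm(8, 3), rnorm(8))
  expect_gte(r3$p_value, 1 / (r3$n_used + 1))
  expect_error(paired_permutation_test(1:4, 1:5), "invalid-argument")
  expect_error(paired_permutation_test(1:2, 2:3), "invalid-argument")
})

test_that("Monte-Carlo p-values agree with enumeration within binomial error", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    x <- rnorm(n, 0.4); y <- rnorm(n)
    ex <- paired_permutation_test(x, y, stats_config(n_permutations = 10000))
    expect_true(ex$exhaustive)
    mc <- paired_permutation_test(x, y,
                                  stats_config(n_permutations = 2000,
                                               rng_seed = i),
                                  force_monte_carlo = TRUE)
    expect_false(mc$exhaustive)
    se <- sqrt(ex$p_value * (1 - ex$p_value) / mc$n_used)
    expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 2 / mc$n_used)
  }
})

test_that("mixed models recover noiseless relationships exactly", {
  subj <- rep(letters[1:5], each = 6)
  power <- rep(c(9, 7, 5, 3, 2, 1), 5) + rep(0:4, each = 6) * 0.3
  vel <- -0.002 * power
  m <- suppressWarnings(suppressMessages(fit_velocity_model(power, vel, subj)))
  expect_equal(m$coefficient, -0.002, tolerance = 1e-6)
  expect_gt(m$r2, 0.999)
  amps <- rep(seq(0, 2.5, by = 0.5), 5)
  pw <- exp(-1.66 * amps + rep(runif(5, 1, 2), each = 6))
  md <- suppressWarnings(suppressMessages(fit_dose_model(pw, amps, subj)))
  expect_equal(md$coefficient, -1.66, tolerance = 1e-6)
  expect_error(fit_dose_model(c(-1, pw[-1]), amps, subj), "invalid-argument")
  expect_error(fit_velocity_model(1:6, 1:6, rep("a", 6)), "invalid-argument")
})

test_that("dose-model inference is calibrated on a small simulated study", {
  # power study: strong coupling detected consistently
  set.seed(21)
  detections <- 0
  for (i in 1:10) {
    subj <- rep(paste0("s", 1:8), each = 6)
    amps <- rep(seq(0, 2.5, by = 0.5), 8)
    pw <- exp(-1.0 * amps + rep(rnorm(8, 2, 0.3), each = 6) + rnorm(48, 0, 0.3))
    m <- suppressMessages(fit_dose_model(pw, amps, subj))
    detections <- detections + (m$p_value < 0.05 && m$coefficient < 0)
  }
  expect_equal(detections, 10)
  # null: no dose dependence, rejections near the nominal level
  rej <- 0
  for (i in 1:100) {
    subj <- rep(paste0("s", 1:8), each = 6)
    amps <- rep(seq(0, 2.5, by = 0.5), 8)
    pw <- exp(rep(rnorm(8, 2, 0.3), each = 6) + rnorm(48, 0, 0.3))
    m <- suppressMessages(fit_dose_model(pw, amps, subj))
    rej <- rej + (m$p_value < 0.05)
  }
  expect_lte(rej / 100, 0.12)
})

test_that("BIC comparison reproduces the reported low- vs high-beta contrast", {
  mk <- function(bic) structure(list(bic = bic, n_obs = 60),
                                class = "mixed_model_result")
  cmp <- compare_models(mk(-393.35), mk(-380.57))
  expect_equal(cmp$delta_bic, 12.78, tolerance = 1e-9)
  expect_equal(cmp$label, "strong")
  expect_equal(cmp$preferred, "a")
  # identical models: no evidence either way
  cmp0 <- compare_models(mk(-100), mk(-100))
  expect_equal(cmp0$delta_bic, 0)
  expect_equal(cmp0$label, "none")
  # the strong-evidence boundary is strict
  expect_equal(compare_models(mk(-106), mk(-100))$label, "not strong")
  # antisymmetry
  a <- mk(-393.35); b <- mk(-380.57)
  expect_equal(compare_models(a, b)$delta_bic, -compare_models(b, a)$delta_bic)
  expect_error(compare_models(mk(-1), structure(list(bic = 0, n_obs = 10),
                                                class = "mixed_model_result")),
               "invalid-argument")
})

test_that("per-subject correlation switches methods on normality", {
  set.seed(31)
  x <- rnorm(50)
  r1 <- per_subject_correlation(x, 2 * x + 1)
  expect_equal(r1$method, "pearson")
  expect_equal(r1$r, 1.0, tolerance = 1e-12)
  xh <- exp(rnorm(50, 0, 1.5)) # heavy-tailed
  r2 <- per_subject_correlation(xh, exp(xh))
  expect_equal(r2$method, "spearman")
  expect_equal(r2$r, 1.0, tolerance = 1e-12)
  r3 <- per_subject_correlation(rep(1, 10), rnorm(10))
  expect_true(r3$degenerate)
  expect_error(per_subject_correlation(1:3, 1:3), "invalid-argument")
  # independent draws: |r| small, rejections near nominal over replicates
  rej <- 0
  for (i in 1:100) {
    r <- per_subject_correlation(rnorm(50), rnorm(50))
    rej <- rej + (r$p < 0.05)
  }
  expect_lte(rej, 12)
})
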