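#' Statistical-inference configuration
#'
#' @param n_permutations Monte-Carlo permutations; default 10000.
#' @param alpha test level.
#' @param delta_bic_strong |dBIC| above which a model comparison is called
#'   strong evidence; default 6.
#' @param rng_seed integer seed for Monte-Carlo permutations.
#' @return a `stats_config` list.
#' @export
stats_config <- function(n_permutations = 10000, alpha = 0.05,
                         delta_bic_strong = 6, rng_seed = 1L) {
  stopifnot(n_permutations >= 100, alpha > 0, alpha < 1)
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 delta_bic_strong = delta_bic_strong,
                 rng_seed = as.integer(rng_seed)),
            class = "stats_config")
}

#' Paired Monte-Carlo permutation test
#'
#' Tests the paired mean difference `mean(x - y)` against the sign-flip null:
#' each pair difference has its sign flipped independently. When the full
#' sign-flip group is no larger than `n_permutations` (`2^n <=
#' n_permutations`) the null is enumerated exhaustively and the p-value is
#' the exact proportion `#{|perm| >= |obs|} / 2^n`; otherwise
#' `n_permutations` random flips are drawn and the p-value uses the +1
#' correction `( #{|perm| >= |obs|} + 1 ) / (n_used + 1)`. Two-sided.
#'
#' @param x,y paired samples of equal length >= 3.
#' @param cfg a `stats_config`.
#' @param force_monte_carlo use random flips even when enumeration would be
#'   feasible (for calibration studies of the Monte-Carlo error).
#' @return a `permutation_result`: `observed_stat`, `p_value`, `n_used`,
#'   `exhaustive`.
#' @export
paired_permutation_test <- function(x, y, cfg = stats_config(),
                                    force_monte_carlo = FALSE) {
  if (length(x) != length(y))
    stop("invalid-argument: x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("invalid-argument: need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("invalid-argument: missing pairs")
  d <- x - y
  obs <- mean(d)
  exhaustive <- 2^n <= cfg$n_permutations && !force_monte_carlo
  if (exhaustive) {
    n_used <- 2^n
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- abs(signs %*% d) / n
    p <- sum(perm >= abs(obs) - 1e-12) / n_used
  } else {
    n_used <- cfg$n_permutations
    perm <- with_seed(cfg$rng_seed, {
      signs <- matrix(sample(c(-1, 1), n_used * n, replace = TRUE), n_used, n)
      abs(signs %*% d) / n
    })
    p <- (sum(perm >= abs(obs) - 1e-12) + 1) / (n_used + 1)
  }
  structure(list(observed_stat = obs, p_value = p, n_used = n_used,
                 exhaustive = exhaustive),
            class = "permutation_result")
}

# shared machinery of the two mixed models: ML fit, Satterthwaite p for the
# slope, marginal (fixed-effects) pseudo-R2 by variance decomposition
fit_lmm <- function(response, predictor, subject, formula_label) {
  dat <- data.frame(y = response, x = predictor,
                    subject = factor(subject))
  if (nlevels(dat$subject) < 2)
    stop("invalid-argument: need at least 2 subjects")
  if (min(table(dat$subject)) < 3)
    stop("invalid-argument: need at least 3 observations per subject")
  fit <- lmerTest::lmer(y ~ x + (1 | subject), data = dat, REML = FALSE)
  co <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_ranef <- sum(vc$vcov[vc$grp != "Residual"])
  var_resid <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- stats::var(stats::model.matrix(fit) %*% lme4::fixef(fit))[1]
  structure(list(
    coefficient = co["x", "Estimate"], se = co["x", "Std. Error"],
    p_value = co["x", "Pr(>|t|)"],
    r2 = var_fixed / (var_fixed + var_ranef + var_resid),
    bic = stats::BIC(fit), n_obs = nrow(dat),
    n_groups = nlevels(dat$subject),
    singular = lme4::isSingular(fit),
    formula_label = formula_label, fit = fit
  ), class = "mixed_model_result")
}

#' Mixed-effects biomarker-velocity model
#'
#' Linear mixed model `velocity ~ power + (1 | subject)` fitted by maximum
#' likelihood (so BICs are comparable across fixed-effect choices). Returns
#' the slope of power, its Satterthwaite p-value, the marginal
#' (fixed-effects) pseudo-R2 and the BIC. A singular random-effects fit is
#' reported via the `singular` flag, not silently.
#'
#' @param power band power per observation (% total sum).
#' @param velocity tap velocity per observation (z-units).
#' @param subject grouping labels.
#' @return a `mixed_model_result`.
#' @export
fit_velocity_model <- function(power, velocity, subject) {
  fit_lmm(velocity, power, subject, "velocity ~ power + (1|subject)")
}

#' Mixed-effects dose-response model
#'
#' Band power is logarithmized (natural log) — the suppression is
#' exponential in stimulation amplitude, so log-power is linear in dose —
#' and regressed on amplitude with a random intercept per subject, by
#' maximum likelihood. The slope is the log-power change per mA.
#'
#' @param power band power per observation (% total sum), strictly positive.
#' @param amplitude_mA stimulation amplitude per observation.
#' @param subject grouping labels.
#' @return a `mixed_model_result`.
#' @export
fit_dose_model <- function(power, amplitude_mA, subject) {
  if (any(power <= 0))
    stop("invalid-argument: non-positive power (log undefined)")
  fit_lmm(log(power), amplitude_mA, subject,
          "log(power) ~ amplitude + (1|subject)")
}

#' BIC model comparison
#'
#' `delta_bic = bic_b - bic_a`; evidence is "strong" when `|delta| >
#' delta_bic_strong` (strictly), preferring the lower-BIC model.
#'
#' @param a,b `mixed_model_result`s fitted on the same observations.
#' @param cfg a `stats_config`.
#' @return list `delta_bic`, `preferred` ("a"/"b"/"none"), `label`
#'   ("strong"/"not strong"/"none").
#' @export
compare_models <- function(a, b, cfg = stats_config()) {
  stopifnot(inherits(a, "mixed_model_result"),
            inherits(b, "mixed_model_result"))
  if (a$n_obs != b$n_obs)
    stop("invalid-argument: models fitted on different observation counts")
  delta <- b$bic - a$bic
  list(delta_bic = delta,
       preferred = if (delta > 0) "a" else if (delta < 0) "b" else "none",
       label = if (delta == 0) "none"
       else if (abs(delta) > cfg$delta_bic_strong) "strong" else "not strong")
}

#' Per-subject correlation with a normality gate
#'
#' Shapiro-Wilk tests each series; Pearson correlation when both are
#' compatible with normality (p >= 0.05), Spearman otherwise. The method
#' actually used is recorded.
#'
#' @param x,y paired series, n >= 4.
#' @return a `correlation_result`: `method`, `r`, `p`, `normality_p`
#'   (length 2), or `degenerate = TRUE` when an input is constant.
#' @export
per_subject_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4)
    stop("invalid-argument: need >= 4 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(method = NA_character_, r = NA_real_, p = NA_real_,
                          normality_p = c(NA_real_, NA_real_),
                          degenerate = TRUE),
                     class = "correlation_result"))
  np <- c(stats::shapiro.test(x)$p.value, stats::shapiro.test(y)$p.value)
  method <- if (all(np >= 0.05)) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  structure(list(method = method, r = unname(ct$estimate), p = ct$p.value,
                 normality_p = np, degenerate = FALSE),
            class = "correlation_result")
}
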