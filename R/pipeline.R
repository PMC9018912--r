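#' Simulate a cohort of sensing hemispheres
#'
#' Each hemisphere gets its own ground truth (sampled via
#' [sample_ground_truth()]) and its own maximum tolerated stimulation
#' amplitude (the side-effect threshold), so group sizes shrink toward
#' higher amplitudes as in a real monopolar review. Per-hemisphere seeds are
#' derived deterministically from the master seed.
#'
#' @param n_hemispheres cohort size; default 10.
#' @param seed master integer seed.
#' @param max_amplitudes_mA vector of per-hemisphere side-effect thresholds
#'   to sample from (with `max_amp_probs`), or length `n_hemispheres` to fix
#'   them.
#' @param max_amp_probs sampling probabilities.
#' @param n_ecg_contaminated number of hemispheres to contaminate with a
#'   strong cardiac artifact (QC-fodder); default 0.
#' @param truths optional list of `ground_truth` objects (overrides
#'   sampling).
#' @param ... passed to [make_protocol()] (e.g. `rest_duration_s`,
#'   `n_tap_blocks`) and [sample_ground_truth()] (`*_range` arguments).
#' @return a `cohort`: list of hemisphere entries, each with `id`,
#'   `hemisphere`, `protocol`, `truth`, `session`, `accel`.
#' @export
simulate_cohort <- function(n_hemispheres = 10, seed = 1L,
                            max_amplitudes_mA = c(1.5, 2, 2.5),
                            max_amp_probs = c(0.1, 0.3, 0.6),
                            n_ecg_contaminated = 0, truths = NULL, ...) {
  dots <- list(...)
  proto_args <- dots[names(dots) %in% names(formals(make_protocol))]
  truth_args <- dots[names(dots) %in% names(formals(sample_ground_truth))]
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, 3 * n_hemispheres))
  if (is.null(truths))
    truths <- do.call(sample_ground_truth,
                      c(list(n = n_hemispheres, seed = sub_seeds[1]), truth_args))
  max_amps <- with_seed(sub_seeds[2], {
    if (length(max_amplitudes_mA) == n_hemispheres) max_amplitudes_mA
    else sample(max_amplitudes_mA, n_hemispheres, replace = TRUE,
                prob = max_amp_probs)
  })
  ecg_idx <- with_seed(sub_seeds[3],
                       sample(n_hemispheres, min(n_ecg_contaminated, n_hemispheres)))
  lapply(seq_len(n_hemispheres), function(i) {
    proto <- do.call(make_protocol,
                     c(list(max_amplitude_mA = max_amps[i]), proto_args))
    id <- sprintf("hem%02d", i)
    side <- if (i %% 2 == 1) "left" else "right"
    sess <- simulate_lfp(proto, truths[[i]], seed = sub_seeds[i + n_hemispheres],
                         subject_id = id, hemisphere = side)
    if (i %in% ecg_idx)
      sess <- inject_ecg_artifact(sess, truths[[i]]$ecg_bpm,
                                  6 * stats::sd(sess$channels[[1]]$samples))
    acc <- if (proto$n_tap_blocks > 0)
      simulate_accelerometer(proto, truths[[i]],
                             seed = sub_seeds[i + 2 * n_hemispheres])
    list(id = id, hemisphere = side, protocol = proto, truth = truths[[i]],
         session = sess, accel = acc)
  })
}

#' Write a simulated cohort to disk
#'
#' One session JSON and (when tapping blocks exist) one accelerometer CSV
#' per hemisphere, plus `ground_truth.json` with every hemisphere's
#' generative parameters.
#'
#' @param cohort from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- list()
  for (h in cohort) {
    write_session(h$session, file.path(dir, paste0(h$id, "_session.json")))
    if (!is.null(h$accel))
      write_accel_csv(h$accel, file.path(dir, paste0(h$id, "_accel.csv")))
    gt[[h$id]] <- unclass(h$truth)
  }
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Analyze one hemisphere's merged session
#'
#' QC, zero-phase filtering, Morlet decomposition, total-sum normalization,
#' per-step 30 s rest spectra and band powers, beta-peak detection, tap
#' velocities, and post-cessation baseline recovery.
#'
#' @param session a `session_recording` (LFP channels; merged `accel_z`
#'   channel or `accel` given separately for the velocity analysis).
#' @param accel optional `accel_trace`, merged in before analysis.
#' @param cfg a `spectral_config`.
#' @param mcfg a `movement_config`.
#' @param fspec a `filter_spec`.
#' @param run_qc set FALSE to skip artifact QC (e.g. on generator output
#'   known to be clean in calibration studies).
#' @param ecg_threshold,aliasing_threshold QC thresholds.
#' @return an `hemisphere_result` list: `qc`, `included`, `steps`,
#'   `spectra` (per-step `normalized_spectrum`), `bands` (data.frame
#'   step x band powers), `peaks` (per-step `peak_estimate`), `velocity`
#'   (a `velocity_summary` or NULL), `recovery` (a `recovery_profile` or
#'   NULL).
#' @export
analyze_hemisphere <- function(session, accel = NULL,
                               cfg = spectral_config(),
                               mcfg = movement_config(),
                               fspec = filter_spec(), run_qc = TRUE,
                               ecg_threshold = 0.3, aliasing_threshold = 5) {
  if (!is.null(accel)) session <- merge_accelerometer(session, accel)
  qc <- if (run_qc) qc_session(session, ecg_threshold, aliasing_threshold, cfg)
  else structure(list(decision = "include", reasons = character(0)),
                 class = "qc_report")
  if (qc$decision == "exclude")
    return(structure(list(qc = qc, included = FALSE,
                          subject_id = session$subject_id,
                          hemisphere = session$hemisphere),
                     class = "hemisphere_result"))
  filtered <- filter_session(session, fspec)
  fs <- session$sampling_rate_hz
  tfr <- morlet_tfr(filtered$channels[[1]]$samples, fs, cfg)
  tfrn <- normalize_total_sum(tfr, cfg)
  steps <- session_steps(session)
  rests <- session$events[session$events$label == "rest", , drop = FALSE]
  rests <- rests[order(rests$onset_s), ]
  spectra <- lapply(seq_len(nrow(steps)), function(i)
    rest_spectrum(tfrn, rests[i, ], cfg))
  bands <- do.call(rbind, lapply(seq_len(nrow(steps)), function(i) {
    data.frame(step_index = i, step_mA = steps$step_mA[i],
               band = names(all_bands()),
               power_pct = vapply(all_bands(), band_power,
                                  numeric(1), spectrum = spectra[[i]]),
               actual_window_s = attr(spectra[[i]], "actual_window_s"),
               row.names = NULL)
  }))
  peaks <- lapply(spectra, detect_beta_peak)
  velocity <- NULL
  az <- which(vapply(session$channels, function(ch) ch$label == mcfg$z_axis_label,
                     logical(1)))
  if (length(az) == 1 && any(session$events$label == "tap_block")) {
    vel <- velocity_trace(session$channels[[az]]$samples, fs, mcfg)
    velocity <- block_velocities(vel, session$events, fs)
  }
  recovery <- NULL
  ramp <- session$events[session$events$label == "ramp_down", , drop = FALSE]
  if (nrow(ramp) == 1) {
    cess <- ramp$onset_s + ramp$duration_s
    recovery <- tryCatch(
      baseline_recovery(tfrn, cess, spectra[[1]], cfg),
      error = function(e) NULL)
  }
  structure(list(qc = qc, included = TRUE, subject_id = session$subject_id,
                 hemisphere = session$hemisphere, steps = steps,
                 spectra = spectra, bands = bands, peaks = peaks,
                 velocity = velocity, recovery = recovery),
            class = "hemisphere_result")
}

#' Run the full pipeline over a cohort
#'
#' QC-screens every hemisphere, analyzes the survivors, and assembles the
#' cohort report: per-step band-power means, per-step relative velocities,
#' paired permutation tests of each stimulated step against the 0 mA
#' baseline, the mixed-effects dose-response and biomarker-velocity models
#' per band with BIC comparison of low vs high beta, per-subject
#' correlations, the peak table and the recovery table. Per-step statistics
#' use only the hemispheres that reached that step (group sizes shrink with
#' amplitude). Dose and velocity models use the ascending-amplitude steps;
#' the post-DBS OFF step is governed by washout, not dose, and is reported
#' separately.
#'
#' @param cohort a list of hemisphere entries (`simulate_cohort()` output)
#'   or of `session_recording`s (accelerometer merged or absent).
#' @param cfg,mcfg,fspec,stats_cfg analysis configurations.
#' @param run_qc set FALSE to skip artifact QC.
#' @param ecg_threshold,aliasing_threshold QC thresholds.
#' @return a `cohort_report`; see Details.
#' @export
run_cohort <- function(cohort, cfg = spectral_config(),
                       mcfg = movement_config(), fspec = filter_spec(),
                       stats_cfg = stats_config(), run_qc = TRUE,
                       ecg_threshold = 0.3, aliasing_threshold = 5) {
  results <- lapply(cohort, function(h) {
    if (inherits(h, "session_recording"))
      analyze_hemisphere(h, cfg = cfg, mcfg = mcfg, fspec = fspec,
                         run_qc = run_qc, ecg_threshold = ecg_threshold,
                         aliasing_threshold = aliasing_threshold)
    else
      analyze_hemisphere(h$session, h$accel, cfg = cfg, mcfg = mcfg,
                         fspec = fspec, run_qc = run_qc,
                         ecg_threshold = ecg_threshold,
                         aliasing_threshold = aliasing_threshold)
  })
  included <- Filter(function(r) r$included, results)
  excluded <- Filter(function(r) !r$included, results)
  exclusion_table <- if (length(excluded)) data.frame(
    subject_id = vapply(excluded, `[[`, "", "subject_id"),
    reasons = vapply(excluded, function(r) paste(r$qc$reasons, collapse = "; "), "")
  ) else data.frame(subject_id = character(0), reasons = character(0))
  if (length(included) < 2)
    stop("cohort-error: fewer than 2 hemispheres after QC (",
         paste(sprintf("%s: %s", exclusion_table$subject_id,
                       exclusion_table$reasons), collapse = " | "), ")")

  band_table <- do.call(rbind, lapply(included, function(r) {
    b <- r$bands
    b$subject_id <- r$subject_id
    b$hemisphere <- r$hemisphere
    n_steps <- nrow(r$steps)
    b$condition <- ifelse(b$step_index == n_steps & b$step_mA == 0,
                          "OFF_post", sprintf("%g mA", b$step_mA))
    b$peak_hz <- vapply(b$step_index, function(i) r$peaks[[i]]$freq_hz,
                        numeric(1))
    b
  }))

  asc <- band_table[band_table$condition != "OFF_post", ]
  step_band <- stats::aggregate(power_pct ~ band + step_mA, asc,
                                function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  step_band <- do.call(data.frame, step_band)
  names(step_band) <- c("band", "step_mA", "mean_power_pct", "sd_power_pct", "n")

  velocity_table <- do.call(rbind, lapply(included, function(r) {
    if (is.null(r$velocity)) return(NULL)
    v <- r$velocity$per_step
    v$subject_id <- r$subject_id
    n_steps <- nrow(r$steps)
    v$condition <- ifelse(v$step_index == n_steps & v$step_mA == 0,
                          "OFF_post", sprintf("%g mA", v$step_mA))
    v
  }))
  step_velocity <- NULL
  if (!is.null(velocity_table)) {
    va <- velocity_table[velocity_table$condition != "OFF_post", ]
    step_velocity <- do.call(data.frame,
                             stats::aggregate(relative_velocity ~ step_mA, va,
                                              function(v) c(mean = mean(v),
                                                            sd = stats::sd(v),
                                                            n = length(v))))
    names(step_velocity) <- c("step_mA", "mean_relative_velocity",
                              "sd_relative_velocity", "n")
  }

  # paired permutation: each stimulated step vs the 0 mA baseline, per band,
  # over the hemispheres that reached that step
  perm_table <- do.call(rbind, lapply(names(all_bands()), function(bn) {
    ba <- asc[asc$band == bn, ]
    amps <- sort(unique(ba$step_mA[ba$step_mA > 0]))
    do.call(rbind, lapply(amps, function(a) {
      on <- ba[ba$step_mA == a, ]
      off <- ba[ba$step_mA == 0 & ba$subject_id %in% on$subject_id, ]
      on <- on[match(off$subject_id, on$subject_id), ]
      if (nrow(on) < 3) return(NULL)
      pr <- paired_permutation_test(off$power_pct, on$power_pct, stats_cfg)
      data.frame(band = bn, step_mA = a, n = nrow(on),
                 mean_diff = pr$observed_stat, p_value = pr$p_value,
                 exhaustive = pr$exhaustive)
    }))
  }))

  models <- list()
  for (bn in names(all_bands())) {
    ba <- asc[asc$band == bn, ]
    models[[paste0("dose_", bn)]] <-
      fit_dose_model(ba$power_pct, ba$step_mA, ba$subject_id)
    if (!is.null(velocity_table)) {
      key <- paste(ba$subject_id, ba$step_index)
      va <- velocity_table[velocity_table$condition != "OFF_post", ]
      vkey <- paste(va$subject_id, va$step_index)
      m <- match(key, vkey)
      ok <- !is.na(m)
      models[[paste0("velocity_", bn)]] <-
        fit_velocity_model(ba$power_pct[ok], va$relative_velocity[m[ok]],
                           ba$subject_id[ok])
    }
  }
  comparisons <- list(
    dose_low_vs_high_beta = compare_models(models$dose_low_beta,
                                           models$dose_high_beta, stats_cfg))
  if (!is.null(models$velocity_low_beta))
    comparisons$velocity_low_vs_high_beta <-
      compare_models(models$velocity_low_beta, models$velocity_high_beta,
                     stats_cfg)

  correlations <- NULL
  if (!is.null(velocity_table)) {
    correlations <- do.call(rbind, lapply(included, function(r) {
      if (is.null(r$velocity)) return(NULL)
      lb <- r$bands[r$bands$band == "low_beta", ]
      v <- r$velocity$per_step
      m <- match(v$step_index, lb$step_index)
      if (sum(!is.na(m)) < 4) return(NULL)
      ct <- per_subject_correlation(lb$power_pct[m[!is.na(m)]],
                                    v$relative_velocity[!is.na(m)])
      data.frame(subject_id = r$subject_id, method = ct$method, r = ct$r,
                 p = ct$p)
    }))
  }

  recovery_table <- do.call(rbind, lapply(included, function(r) {
    if (is.null(r$recovery)) return(NULL)
    data.frame(subject_id = r$subject_id,
               recovery_time_s = r$recovery$recovery_time_s,
               recovered = r$recovery$recovered)
  }))

  report <- structure(list(
    n_input = length(cohort), n_included = length(included),
    exclusions = exclusion_table, hemispheres = included,
    band_table = band_table, step_band = step_band,
    velocity_table = velocity_table, step_velocity = step_velocity,
    permutation_table = perm_table, models = models,
    comparisons = comparisons, correlations = correlations,
    recovery_table = recovery_table
  ), class = "cohort_report")
  report$best_effect <- tryCatch(best_effect_grouping(report),
                                 error = function(e) NULL)
  report
}

#' Best-clinical-effect grouping
#'
#' Operationalizes "best clinical effect" from the accelerometer alone: per
#' hemisphere, the step with maximal per-step mean tap velocity (ties broken
#' toward the lower amplitude). Spectra are then averaged across hemispheres
#' in three conditions: OFF pre-DBS, best effect, OFF post-DBS, with the
#' per-condition beta-peak estimates.
#'
#' @param report a `cohort_report`.
#' @return list with `best_steps` (data.frame subject_id, step_index,
#'   step_mA), `grouped_spectra` (named list of mean `normalized_spectrum`s),
#'   `peak_table` (per hemisphere x condition) and `band_summary` (mean/sd
#'   band powers per condition).
#' @export
best_effect_grouping <- function(report) {
  stopifnot(inherits(report, "cohort_report"))
  hems <- Filter(function(r) !is.null(r$velocity), report$hemispheres)
  if (!length(hems)) stop("invalid-argument: no velocity analyses in report")
  rows <- list(); spectra <- list(OFF_pre = list(), best = list(), OFF_post = list())
  peak_rows <- list(); band_rows <- list()
  for (r in hems) {
    v <- r$velocity$per_step
    best <- v[order(-v$mean_velocity, v$step_mA), ][1, ]
    rows[[r$subject_id]] <- data.frame(subject_id = r$subject_id,
                                       step_index = best$step_index,
                                       step_mA = best$step_mA)
    n_steps <- nrow(r$steps)
    idx <- c(OFF_pre = 1L, best = best$step_index, OFF_post = n_steps)
    for (cond in names(idx)) {
      sp <- r$spectra[[idx[[cond]]]]
      spectra[[cond]][[r$subject_id]] <- sp
      pk <- r$peaks[[idx[[cond]]]]
      peak_rows[[paste(r$subject_id, cond)]] <-
        data.frame(subject_id = r$subject_id, condition = cond,
                   peak_hz = pk$freq_hz, found = pk$found)
      for (bn in names(all_bands()))
        band_rows[[paste(r$subject_id, cond, bn)]] <-
          data.frame(subject_id = r$subject_id, condition = cond, band = bn,
                     power_pct = band_power(sp, band_definition(bn)))
    }
  }
  grouped <- lapply(spectra, function(sl) {
    structure(list(power_pct = rowMeans(sapply(sl, `[[`, "power_pct")),
                   freqs_hz = sl[[1]]$freqs_hz),
              class = "normalized_spectrum")
  })
  bands <- do.call(rbind, band_rows)
  band_summary <- do.call(data.frame,
                          stats::aggregate(power_pct ~ condition + band, bands,
                                           function(v) c(mean = mean(v),
                                                         sd = stats::sd(v))))
  names(band_summary) <- c("condition", "band", "mean_power_pct", "sd_power_pct")
  list(best_steps = do.call(rbind, rows),
       grouped_spectra = grouped,
       peak_table = do.call(rbind, peak_rows),
       band_summary = band_summary)
}

#' Serialize a cohort report's tables
#'
#' Writes the report's data tables as CSV and a JSON summary (tables plus
#' model records) with deterministic content, so identical configurations
#' yield byte-identical files.
#'
#' @param report a `cohort_report`.
#' @param dir output directory.
#' @return invisibly, the JSON path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("band_table", "step_band", "velocity_table", "step_velocity",
            "permutation_table", "correlations", "recovery_table",
            "exclusions")
  for (tb in tabs)
    if (!is.null(report[[tb]]))
      data.table::fwrite(report[[tb]], file.path(dir, paste0(tb, ".csv")))
  mod <- lapply(report$models, function(m)
    m[c("coefficient", "se", "p_value", "r2", "bic", "n_obs", "n_groups",
        "singular", "formula_label")])
  js <- list(n_input = report$n_input, n_included = report$n_included,
             models = mod, comparisons = report$comparisons,
             best_steps = report$best_effect$best_steps,
             band_summary = report$best_effect$band_summary)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}
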