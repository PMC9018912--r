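#!/usr/bin/env Rscript

# Stage 3 — spectral quantification.
#
# For every included hemisphere: zero-phase Butterworth filtering (5-98 Hz,
# 48-52 Hz notch), Morlet decomposition (8 cycles, 1 Hz resolution),
# normalization to % of total 3-47/53-97 Hz power, 30 s rest spectra per
# stimulation step, band powers (theta/alpha/low/high/total beta), beta-peak
# detection, and the post-cessation low-beta recovery profile.

library(betadose)

cohort_dir <- "scratch/cohort"
qc <- data.table::fread("results/qc.csv")
keep <- qc$subject_id[qc$decision == "include"]

spectra <- list(); recovery <- list(); peaks <- list()
for (id in keep) {
  s <- read_session(file.path(cohort_dir, paste0(id, "_session.json")))
  h <- analyze_hemisphere(s, run_qc = FALSE)
  b <- h$bands
  b$subject_id <- id
  b$peak_hz <- vapply(b$step_index, function(i) h$peaks[[i]]$freq_hz,
                      numeric(1))
  spectra[[id]] <- b
  if (!is.null(h$recovery))
    recovery[[id]] <- data.frame(subject_id = id,
                                 second = seq_along(h$recovery$rel_low_beta),
                                 rel_low_beta = h$recovery$rel_low_beta,
                                 recovery_time_s = h$recovery$recovery_time_s)
  lb <- b[b$band == "low_beta", ]
  message(sprintf("  %s: low-beta OFF %.1f%%, last step %.2f%%, peak %s Hz",
                  id, lb$power_pct[1], lb$power_pct[nrow(lb) - 1],
                  format(b$peak_hz[1])))
}
data.table::fwrite(do.call(rbind, spectra), "results/spectra.csv")
data.table::fwrite(do.call(rbind, recovery), "results/recovery.csv")
message("Band powers in results/spectra.csv; washout in results/recovery.csv")
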