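#!/usr/bin/env Rscript

# Stage 2 — automated artifact screening.
#
# Replaces visual inspection: each hemisphere is scored for cardiac
# bleed-through (periodicity of the delta-range envelope) and stimulation
# aliasing (narrow tones above 70 Hz in the high-resolution periodogram).
# Either flag excludes the hemisphere, mirroring the exclusion mechanism
# applied to real sensing-IPG recordings.

library(betadose)

cohort_dir <- "scratch/cohort"
files <- sort(list.files(cohort_dir, pattern = "_session\\.json$",
                         full.names = TRUE))
stopifnot(length(files) > 0)

rows <- lapply(files, function(f) {
  s <- read_session(f)
  q <- qc_session(s)
  message(sprintf("  %s: ECG %.2f, aliasing %.1f -> %s", s$subject_id,
                  q$ecg_score, q$aliasing_score, q$decision))
  data.frame(subject_id = s$subject_id, hemisphere = s$hemisphere,
             ecg_score = q$ecg_score, ecg_flag = q$ecg_flag,
             aliasing_score = q$aliasing_score,
             aliasing_flag = q$aliasing_flag, decision = q$decision,
             reasons = paste(q$reasons, collapse = "; "))
})
qc <- do.call(rbind, rows)
data.table::fwrite(qc, "results/qc.csv")
message(sum(qc$decision == "include"), " of ", nrow(qc),
        " hemispheres pass QC; table in results/qc.csv")
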