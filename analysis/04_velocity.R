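#!/usr/bin/env Rscript

# Stage 4 — tapping-velocity quantification.
#
# Accelerometer z-axes are merged into the LFP sessions (anti-aliased
# resampling to 250 Hz), transformed to smoothed rectified velocity,
# z-scored over the recording, and averaged per tapping block and per
# stimulation step, relative to the 0 mA baseline.

library(betadose)

cohort_dir <- "scratch/cohort"
qc <- data.table::fread("results/qc.csv")
keep <- qc$subject_id[qc$decision == "include"]

rows <- list()
for (id in keep) {
  s <- read_session(file.path(cohort_dir, paste0(id, "_session.json")))
  a <- read_accel_csv(file.path(cohort_dir, paste0(id, "_accel.csv")))
  m <- merge_accelerometer(s, a)
  v <- velocity_trace(m$channels[[length(m$channels)]]$samples,
                      m$sampling_rate_hz)
  bv <- block_velocities(v, m$events, m$sampling_rate_hz)
  ps <- bv$per_step
  ps$subject_id <- id
  rows[[id]] <- ps
  message(sprintf("  %s: relative velocity at max dose %.2f", id,
                  ps$relative_velocity[which.max(ps$step_mA)]))
}
data.table::fwrite(do.call(rbind, rows), "results/velocity.csv")
message("Per-step velocities in results/velocity.csv")
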