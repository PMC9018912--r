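#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohort.
#
# Ten sensing hemispheres undergo a stepped monopolar review: stimulation
# raised in 0.5 mA steps up to a per-hemisphere side-effect threshold, 60 s
# rest plus two 10 s finger-tapping blocks per step, then a ~23 s ramp-down
# and an OFF-post step. Each hemisphere has its own beta peak (12-19 Hz),
# suppression rate and velocity coupling, recorded in the ground-truth file.
#
# Bulk session data go to scratch/cohort/ (large, regenerable); the
# ground-truth table is kept with the results.

library(betadose)

seed <- 1L
cohort_dir <- "scratch/cohort"
dir.create("results", showWarnings = FALSE)

message("Simulating 10 hemispheres (seed ", seed, ") ...")
cohort <- simulate_cohort(10, seed = seed)
write_cohort(cohort, cohort_dir)
invisible(file.copy(file.path(cohort_dir, "ground_truth.json"),
                    "results/cohort_ground_truth.json", overwrite = TRUE))

for (h in cohort) {
  message(sprintf(
    "  %s (%s): peak %.1f Hz, k = %.2f /mA, coupling %.2f, max %.1f mA",
    h$id, h$hemisphere, h$truth$beta_peak_hz, h$truth$suppression_k,
    h$truth$velocity_coupling_c, max(h$protocol$step_amplitudes_mA)))
}
message("Sessions written under ", cohort_dir)
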