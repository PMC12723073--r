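#!/usr/bin/env Rscript
# Simulate the study cohorts: an effect-bearing cohort whose coupled channel
# pairs phase-lock only after the pulse (kappa 0 -> 5 on theta, alpha and
# beta-2 pairs), and a sham-like null cohort with no coupling change.
# Writes the epoch containers consumed by the later stages.

suppressMessages(library(plvnet))
dir.create("results", showWarnings = FALSE)

effect <- generate_cohort(effect_cohort_config(seed = 1))
null <- generate_cohort(null_cohort_config(seed = 2))

write_cohort(effect, "results/cohort_effect.rds")
write_cohort(null, "results/cohort_null.rds")

cfg <- attr(effect, "config")
message(sprintf(
  "Simulated %d + %d subjects: %d channels x %d trials x 2 s at %g Hz",
  cfg$n_subjects, attr(null, "config")$n_subjects,
  cfg$n_channels, cfg$n_trials, cfg$fs_hz))
message(sprintf("Coupled pairs: %s",
                paste(vapply(cfg$couplings, function(cs)
                  sprintf("(%d,%d) %g-%g Hz", cs$pair[1], cs$pair[2],
                          cs$band_hz[1], cs$band_hz[2]), ""),
                  collapse = ", ")))
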