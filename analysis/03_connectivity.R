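#!/usr/bin/env Rscript
# Wavelet phase-locking connectivity: for every subject, window (baseline
# -1000..0 ms, response 15..315 ms) and band (theta..gamma + 4-70 Hz
# broadband), build the channel x channel PLV and ciPLV matrices from
# COI-valid Morlet coefficients.

suppressMessages(library(plvnet))
dir.create("results", showWarnings = FALSE)

for (tag in c("effect", "null")) {
  cohort <- read_cohort(sprintf("results/cohort_%s.rds", tag))
  mats <- list()
  for (k in seq_along(cohort))
    mats <- c(mats, connectivity_matrices(cohort[[k]],
                                          estimators = c("plv", "ciplv"),
                                          subject = k))
  saveRDS(mats, sprintf("results/connectivity_%s.rds", tag))
  qc <- qc_summary(mats)
  write.table(as.data.frame(qc),
              sprintf("results/connectivity_qc_%s.tsv", tag),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s cohort: %d matrices; all symmetric: %s; all in [0,1]: %s",
    tag, nrow(qc), all(qc$symmetric), all(qc$in_bounds)))
  glob <- qc[qc$band == "global" & qc$estimator == "plv", ]
  message(sprintf("  global-band PLV mean weight: pre %.3f, post %.3f",
                  mean(glob$mean[glob$window == "prestimulus"]),
                  mean(glob$mean[glob$window == "poststimulus"])))
}
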