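#!/usr/bin/env Rscript
# Weighted graph metrics per subject, window, band and estimator:
# connectivity strength (mean edge weight), clustering coefficient
# (geometric-mean triangle intensity, degree-normalised) and
# characteristic path length (mean shortest 1/w-distance).

suppressMessages(library(plvnet))
dir.create("results", showWarnings = FALSE)

for (tag in c("effect", "null")) {
  cohort <- read_cohort(sprintf("results/cohort_%s.rds", tag))
  metrics <- compute_cohort_metrics(cohort,
                                    estimators = c("plv", "ciplv"))
  write.table(as.data.frame(metrics),
              sprintf("results/metrics_%s.tsv", tag),
              sep = "\t", quote = FALSE, row.names = FALSE)
  g <- metrics[metrics$band == "global" & metrics$estimator == "plv", ]
  for (pm in c("cs", "clc", "pl")) {
    pre <- mean(g$value[g$parameter == pm & g$window == "prestimulus"])
    post <- mean(g$value[g$parameter == pm & g$window == "poststimulus"])
    message(sprintf("%s cohort, global-band %s (PLV): pre %.4f  post %.4f",
                    tag, toupper(pm), pre, post))
  }
}
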