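#!/usr/bin/env Rscript
# Paired pre/post comparisons per parameter and band, one-tailed in the
# prespecified directions (CS and ClC increase after the pulse, PL
# decreases), Bonferroni-corrected (alpha/18 for the 6-band active layout;
# the null cohort is also scored against the same 18-test family).

suppressMessages(library(plvnet))
dir.create("results", showWarnings = FALSE)

for (tag in c("effect", "null")) {
  metrics <- tibble::as_tibble(read.table(
    sprintf("results/metrics_%s.tsv", tag), header = TRUE, sep = "\t"))
  for (est in c("plv", "ciplv")) {
    res <- compare_windows(metrics[metrics$estimator == est, ],
                           design = "active")
    write.table(as.data.frame(res),
                sprintf("results/stats_%s_%s.tsv", tag, est),
                sep = "\t", quote = FALSE, row.names = FALSE)
    n_sig <- sum(res$significant_bonferroni)
    message(sprintf("%s cohort, %s: %d / %d comparisons significant at %.2g",
                    tag, toupper(est), n_sig, nrow(res),
                    unique(res$p_threshold)))
    g <- res[res$band == "global", ]
    message(paste(sprintf(
      "  global %s: t(%d) = %.2f, p = %.2g, d = %.2f%s",
      toupper(g$parameter), g$df, g$t, g$p, g$d,
      ifelse(g$significant_bonferroni, " *", "")), collapse = "\n"))
  }
}
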