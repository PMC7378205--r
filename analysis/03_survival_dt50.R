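#!/usr/bin/env Rscript
# Survival analysis: per-well DT50s from the observation log, condition
# means with extension percentages against the vehicle control, and
# Dunnett-corrected significance — the layout of a published survival table.

suppressMessages(library(nemascreen))

log <- read_survival_log("results/data/survival_log.csv")
res <- dt50_results(log, control_label = "control")
utils::write.csv(res, "results/survival_dt50.csv", row.names = FALSE)

cat("survival analysis (mean DT50 +/- SD over wells; N = worms assayed):\n")
for (i in seq_len(nrow(res))) {
  cat(sprintf("  %-14s %5.2f +/- %4.2f d  N=%3d  ext %6s  p %s\n",
              res$condition[i], res$mean_dt50[i], res$sd_dt50[i],
              res$n_worms[i],
              ifelse(is.na(res$extension_pct[i]), "-",
                     sprintf("%+.1f%%", res$extension_pct[i])),
              ifelse(is.na(res$p_adj[i]), "-",
                     format.pval(res$p_adj[i], digits = 2))))
}
an <- attr(res, "anova")
cat(sprintf("one-way ANOVA: F = %.2f, p = %.2g\n", an$f_statistic, an$f_p_value))
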