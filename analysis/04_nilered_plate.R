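#!/usr/bin/env Rscript
# Nile red plate analysis: per-experiment condition means, normalization to
# the vehicle control (= 100%), and Bonferroni-corrected comparisons on
# experiment-level values.

suppressMessages(library(nemascreen))

pw <- read_worm_measurements("results/data/nilered_per_worm.csv")
res <- plate_results(pw, control_label = "control")
utils::write.csv(res, "results/nilered_normalized.csv", row.names = FALSE)

cat("Nile red fluorescence, % of vehicle control (mean +/- SD over experiments):\n")
for (i in seq_len(nrow(res))) {
  cat(sprintf("  %-14s %6.1f%% +/- %4.1f  (%d worms) %s\n",
              res$condition[i], res$normalized_pct[i], res$sd_pct[i],
              res$n_worms[i], res$stars[i]))
}
an <- attr(res, "anova")
cat(sprintf("one-way ANOVA: F = %.2f, p = %.2g; Bonferroni family m = %d\n",
            an$f_statistic, an$f_p_value, an$m))
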