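#!/usr/bin/env Rscript
# A-priori sample-size computation for the repeated-measures design:
# alpha 5%, power 90%, minimal meaningful difference 10 ms, variance input
# 10 (sd scale) and 36 Bonferroni comparisons.

suppressMessages(library(ppsbayes))
res <- rm_anova_sample_size(alpha = 0.05, power = 0.90, delta = 10,
                            sigma = 10, m = 36)
cat(sprintf("suggested sample size: %d participants (raw %.2f)\n",
            res$n, res$n_raw))
cat(res$inputs$note, "\n")

grid <- expand.grid(delta = c(5, 10, 15, 20), m = c(1, 36))
grid$n <- mapply(function(d, m) rm_anova_sample_size(delta = d, m = m)$n,
                 grid$delta, grid$m)
write.csv(grid, "results/sample_size_grid.csv", row.names = FALSE)
cat("wrote results/sample_size_grid.csv\n")
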