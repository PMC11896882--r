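#!/usr/bin/env Rscript
# Stage 1: generate the synthetic stem-level census (landscape, two-census
# tree inventory, giant-herb grid, lianas with host links, trait table) and
# summarize how it compares to the field design it emulates.

library(lianascape)

res <- run_pipeline(sim_config(seed = 1), out_dir = "results/simulate",
                    stages = c("simulate", "metrics"))
sim <- res$sim

area_ha <- nrow(sim$quadrats) * 0.04
cat(sprintf("quadrats: %d (%.2f ha); trees: %d; lianas: %d (%.0f stems/ha)\n",
            nrow(sim$quadrats), area_ha, nrow(sim$trees), nrow(sim$lianas),
            nrow(sim$lianas) / area_ha))
cat(sprintf("liana size structure: %.0f%% in 1-2 cm, %.0f%% in 1-5 cm, max %.1f cm\n",
            100 * mean(sim$lianas$diameter <= 2),
            100 * mean(sim$lianas$diameter <= 5), max(sim$lianas$diameter)))
ab <- sort(table(sim$lianas$taxon), decreasing = TRUE)
cat(sprintf("hyperdominance: top-3 taxa hold %.0f%% of stems\n",
            100 * sum(ab[1:3]) / sum(ab)))
cat(sprintf("lianas with an identified host: %.1f%%\n",
            100 * mean(!sim$lianas$hostless)))
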