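#!/usr/bin/env Rscript
# Stage 2: quadrat-scale liana structure (N_L, BA_L, QMD_L) and the eight
# environmental predictors (tree stand variables, canopy height, giant-herb
# cover, relative slope position), plus the collinearity screen.

library(lianascape)

res <- run_pipeline(sim_config(seed = 1), out_dir = "results/metrics",
                    stages = c("simulate", "metrics"))

cat("== Liana structure (per-quadrat distribution) ==\n")
print(summary(res$liana_structure[c("N_L", "BA_L", "QMD_L")]))
cat("\n== Environment (per-quadrat distribution) ==\n")
print(summary(res$env[ENV_VARS]))
cat("\n== Predictor correlation screen (|r| >= 0.7 flagged) ==\n")
scr <- res$env_screen
print(scr[order(-abs(scr$r)), ][1:8, ], row.names = FALSE)
if (!any(scr$flagged)) cat("no predictor pair reaches |r| = 0.7\n")
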