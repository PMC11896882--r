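#!/usr/bin/env Rscript
# Stage 4: liana floristic composition. NSCA of the quadrat x taxon table,
# spatial variogram permutation envelopes (9999 permutations, 11 distance
# classes) for the first two axis scores, then the constrained analyses:
# NSCAIV on the environment and PCCA conditioned on second-order quadrat
# coordinates (999 permutations each).

library(lianascape)

res <- run_pipeline(sim_config(seed = 1), out_dir = "results/ordination",
                    stages = c("simulate", "metrics", "ordination"))

print(res$nsca)
cat(sprintf("first two axes capture %.0f%% of floristic variation\n",
            100 * sum(res$nsca$eigenvalues[1:2]) / res$nsca$total_inertia))
for (a in 1:2) {
  v <- res$variogram[[a]]
  cat(sprintf("axis %d variogram: %d of %d distance classes outside the 95%% envelope\n",
              a, sum(v$classes$outside), nrow(v$classes)))
}
print(res$nscaiv)
print(res$pcca)
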