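#!/usr/bin/env Rscript
# Step 4 — Probabilistic sensitivity analysis.
#
# 1000 iterations; every input drawn with a 10% standard error of its mean
# (lognormal for clinical variables, beta for transition probabilities with
# renormalization, gamma for costs). Writes the per-iteration incremental
# cost/QALY pairs (the cost-effectiveness plane), the acceptability curve,
# and a summary. Seed configurable: Rscript analysis/04_psa.R [seed].

suppressPackageStartupMessages(library(rrmsce))
dir.create("results", showWarnings = FALSE)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 42L

p <- load_parameters(system.file("extdata", "base_case.yaml",
                                 package = "rrmsce"), quiet = TRUE)
psa <- suppressWarnings(run_psa(
  p, settings = list(n_iterations = 1000L, se_fraction = 0.10),
  wtp = 50000, seed = seed
))
write.csv(psa$draws, "results/psa_draws.csv", row.names = FALSE)
curve <- ceac(psa)
write.csv(curve, "results/ceac.csv", row.names = FALSE)

print(psa)
cat(sprintf("Quadrant split: %.1f%% cheaper & better, %.1f%% dearer & better,\n",
            100 * mean(psa$draws$delta_cost < 0 & psa$draws$delta_qalys > 0),
            100 * mean(psa$draws$delta_cost >= 0 & psa$draws$delta_qalys > 0)))
cat(sprintf("               %.1f%% with a QALY loss.\n",
            100 * mean(psa$draws$delta_qalys <= 0)))
cat("Written: results/psa_draws.csv, results/ceac.csv\n")
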