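#!/usr/bin/env Rscript
# Simulate the synthetic cohorts analysed by the downstream scripts.
#
# Writes one run directory per experiment under results/runs/, each with the
# raw tables (choices / trials / EE curves / truth) and a seeded manifest.
# Exp. 1 (active sampling) uses a smaller cohort because every trial
# simulates a full sequential sampling episode.

library(circlequest)

root <- file.path("results", "runs")

m1 <- simulate_run(cohort_config(n_per_group = 6, seed = 101), "exp1",
                   file.path(root, "exp1"))
cat("exp1:", m1$content_hash, "\n")

m2 <- simulate_run(cohort_config(n_per_group = 19, seed = 202), "exp2",
                   file.path(root, "exp2"))
cat("exp2:", m2$content_hash, "\n")

m4 <- simulate_run(cohort_config(n_per_group = 19, seed = 404), "exp4",
                   file.path(root, "exp4"))
cat("exp4:", m4$content_hash, "\n")
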