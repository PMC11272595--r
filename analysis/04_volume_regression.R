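#!/usr/bin/env Rscript
# Structure-behaviour analysis on synthetic volumetry: ICV-adjust simulated
# hippocampal volumes and regress recovered reward sensitivity on them with
# a robust (bisquare) fit.
#
# The volumes are generated here, not by the task model: each subject's
# volume tracks their generative context-attenuation parameter (smaller
# gamma, smaller volume) plus head-size (ICV) dependence and noise, so the
# regression has a known planted relationship to recover.
#
# Requires: analysis/01_simulate.R and analysis/03_passive_sensitivities.R

library(circlequest)

set.seed(777)
truth <- read_cq_csv(file.path("results", "runs", "exp2", "truth.csv"))
sens <- read_cq_csv(file.path("results", "exp2_sensitivities.csv"))
m <- match(sens$subject_id, truth$subject_id)

n <- nrow(sens)
icv <- rnorm(n, 1.5e6, 1.2e5)
volume <- 2400 + 600 * truth$gamma_context[m] +
  0.002 * (icv - 1.5e6) + rnorm(n, 0, 60)

records <- data.frame(subject_id = sens$subject_id, group = sens$group,
                      raw_volume = volume, icv = icv)
adj <- icv_adjust(records)
write_cq_csv(adj, file.path("results", "volumes_adjusted.csv"))

fit <- volume_sensitivity_regression(adj$adjusted_volume,
                                     sens$beta_reward_hat)
out <- data.frame(term = "adjusted_volume", slope = fit$slope,
                  ci_lo = fit$ci[1], ci_hi = fit$ci[2],
                  r_squared = fit$r_squared)
write_cq_csv(out, file.path("results", "volume_regression.csv"))
print(out)
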