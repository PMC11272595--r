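#!/usr/bin/env Rscript
# Passive-choice analyses (Exps. 2 and 4): per-subject logistic
# sensitivities, group contrasts, parameter recovery against the generative
# truth, and confidence calibration.
#
# Requires: analysis/01_simulate.R

library(circlequest)

for (exp_id in c("exp2", "exp4")) {
  run <- file.path("results", "runs", exp_id)
  res <- analyze_run(run, write = FALSE)
  write_cq_csv(res$sensitivities,
               file.path("results", paste0(exp_id, "_sensitivities.csv")))
  write_cq_csv(res$contrasts,
               file.path("results", paste0(exp_id, "_contrasts.csv")))
  if (!is.null(res$recovery))
    write_cq_csv(res$recovery,
                 file.path("results", paste0(exp_id, "_recovery.csv")))
  if (!is.null(res$estimation_accuracy)) {
    acc <- res$estimation_accuracy
    write_cq_csv(data.frame(slope = acc$slope, r_squared = acc$r_squared),
                 file.path("results", paste0(exp_id, "_calibration.csv")))
  }
  cat("==", exp_id, "contrasts ==\n")
  print(res$contrasts[, c("metric", "test", "p_value", "effect_size")])
}
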