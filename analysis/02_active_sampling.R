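#!/usr/bin/env Rscript
# Active-sampling (Exp. 1) analysis: deviation from the optimal sample
# count per condition, the cost-sensitivity index with its group contrast,
# and per-subject extraction rates / inter-sampling intervals.
#
# Requires: analysis/01_simulate.R

library(circlequest)

run <- file.path("results", "runs", "exp1")
res <- analyze_run(run, write = FALSE)

write_cq_csv(res$oversampling_cells,
             file.path("results", "exp1_oversampling_cells.csv"))
write_cq_csv(res$cost_sensitivity,
             file.path("results", "exp1_cost_sensitivity.csv"))
write_cq_csv(res$contrasts,
             file.path("results", "exp1_cost_sensitivity_contrast.csv"))

# extraction rate and sampling speed per subject
trials <- read_cq_csv(file.path(run, "trials.csv"))
curves <- read_cq_csv(file.path(run, "ee_curves.csv"))
subjects <- unique(trials$subject_id)
speed <- do.call(rbind, lapply(subjects, function(sid) {
  cv <- curves[curves$subject_id == sid, ]
  fits <- suppressWarnings(
    fit_extraction_rate(split(cv$ee, cv$trial_id)))
  data.frame(subject_id = sid,
             group = trials$group[match(sid, trials$subject_id)],
             mean_alpha = mean(fits$alpha[!fits$flagged]),
             mean_samples = mean(trials$s_taken[trials$subject_id == sid]),
             mean_isi = mean(trials$mean_isi[trials$subject_id == sid],
                             na.rm = TRUE))
}))
write_cq_csv(speed, file.path("results", "exp1_speed_efficiency.csv"))

print(res$contrasts)
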