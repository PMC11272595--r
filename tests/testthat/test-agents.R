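# Synthetic participants: choice model, sampling policy, confidence.

test_that("a null agent accepts with probability exactly one half", {
  ag <- agent_params("control", beta0 = 0, beta_reward = 0,
                     beta_uncertainty = 0, beta_effort = 0)
  set.seed(1)
  ch <- passive_choice(ag, z_reward = c(-2, 0, 2), z_uncertainty = c(1, 0, -1))
  expect_equal(ch$p_accept, rep(0.5, 3))
})

test_that("acceptance saturates for extreme reward sensitivity", {
  ag <- agent_params("control", beta_reward = 50)
  set.seed(1)
  ch <- passive_choice(ag, z_reward = c(2, -2))
  expect_gt(ch$p_accept[1], 0.999999)
  expect_lt(ch$p_accept[2], 0.000001)
})

test_that("context attenuation scales reward and effort but not uncertainty weights", {
  ag <- agent_params("lesion", gamma_context = 0.4, beta0 = 0)
  with_unc <- passive_choice(ag, z_reward = 1, uncertainty_present = TRUE)
  without <- passive_choice(ag, z_reward = 1, uncertainty_present = FALSE)
  expect_equal(qlogis(with_unc$p_accept), ag$beta_reward * 0.4)
  expect_equal(qlogis(without$p_accept), ag$beta_reward)
  # uncertainty weight unaffected by the attenuation
  u <- passive_choice(ag, z_uncertainty = 1, uncertainty_present = TRUE)
  expect_equal(qlogis(u$p_accept), ag$beta_uncertainty)
})

test_that("confidence is a clipped linear read-out of EE", {
  ag <- agent_params("control", conf_intercept = 100, conf_slope = -1,
                     conf_noise = 0)
  expect_equal(confidence_report(ag, 0), 100)     # clip boundary
  expect_equal(confidence_report(ag, 40), 60)
  expect_equal(confidence_report(ag, 150), 0)     # clipped below
  flat <- agent_params("control", conf_slope = 0, conf_noise = 0,
                       conf_intercept = 70)
  expect_equal(confidence_report(flat, c(10, 90)), c(70, 70))
})

test_that("a prohibitive subjective cost stops sampling immediately", {
  sp <- search_space()
  ag <- agent_params("control", w_cost = 100)
  set.seed(2)
  tr <- active_sampling_episode(ag, trial_economics(95, 5), sp, c(500, 400))
  expect_lte(tr$s_taken, 1)
})

test_that("a cost-blind agent samples until the time budget", {
  sp <- search_space()
  ag <- agent_params("control", w_cost = 0)
  set.seed(3)
  tr <- active_sampling_episode(ag, trial_economics(130, 5), sp, c(500, 400))
  # ISI ~1.1 s against an 18 s budget: the budget, not the value of
  # information, is binding
  expect_gte(tr$s_taken, 8)
  ts <- tr$samples$timestamp
  expect_true(all(diff(ts) > 0))
  expect_lte(max(ts), 18)
})

test_that("trajectories track EE per sample and score the placement", {
  sp <- search_space()
  ag <- agent_params("control")
  set.seed(4)
  econ <- trial_economics(95, 1)
  tr <- active_sampling_episode(ag, econ, sp, c(700, 350))
  expect_length(tr$ee_per_sample, tr$s_taken + 1L)
  expect_equal(tr$score,
               trial_score(econ, tr$s_taken, tr$placement_error))
  expect_true(all(tr$ee_per_sample >= 0))
})

test_that("agent EE trajectories are well described by exponential decay", {
  sp <- search_space()
  set.seed(5)
  ag <- agent_params("control", sampling_jitter = 25, w_cost = 0)
  curves <- lapply(1:6, function(i) {
    ctr <- c(runif(1, 130, sp$width - 130), runif(1, 130, sp$height - 130))
    active_sampling_episode(ag, trial_economics(130, 1), sp, ctr)$ee_per_sample
  })
  fits <- fit_extraction_rate(curves)
  r2 <- vapply(seq_along(curves), function(i) {
    1 - fits$sse[i] / stats::var(curves[[i]])
  }, numeric(1))
  expect_gt(stats::median(r2), 0.8)
})

test_that("cohort simulation is deterministic and emits ground truth", {
  cfg <- cohort_config(n_per_group = 2, seed = 99)
  a <- simulate_cohort(cfg, "exp2")
  b <- simulate_cohort(cfg, "exp2")
  expect_identical(a, b)
  expect_identical(nrow(a$choices), 2L * 2L * 100L)
  expect_identical(nrow(a$truth), 4L)
  expect_setequal(a$truth$group, c("control", "lesion"))
  # truth is emitted alongside behaviour, never derived from it
  expect_true(all(c("beta_reward", "gamma_context") %in% names(a$truth)))
})

test_that("zero-variance parameter distributions give identical same-group agents", {
  cfg <- cohort_config(n_per_group = 3, sds = list(), seed = 12)
  truth <- simulate_cohort(cfg, "exp3")$truth
  ctrl <- truth[truth$group == "control", -1]
  expect_true(all(vapply(ctrl, function(col) length(unique(col)) == 1,
                         logical(1))))
})

test_that("the exp4 cohort records uncertainty presence and catch trials", {
  cfg <- cohort_config(n_per_group = 1, seed = 5)
  res <- simulate_cohort(cfg, "exp4")
  expect_identical(nrow(res$choices), 2L * 210L)
  expect_identical(sum(res$choices$is_catch), 2L * 10L)
  expect_true(all(res$choices$ee[res$choices$uncertainty == "absent"] == 0))
  # confidence reported for uncertainty-present trials
  expect_true(nrow(res$confidence) > 0)
})
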