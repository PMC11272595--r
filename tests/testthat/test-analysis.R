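# Estimation pipeline: sensitivities, calibration, contrasts, volumes.

# choices for one synthetic subject with known standardized-scale betas
make_choices <- function(n, beta_r, beta_u, subject_id = "s01",
                         group = "control") {
  reward <- sample(c(40, 65, 90, 115), n, replace = TRUE)
  ee_val <- runif(n, 16, 94)
  zr <- (reward - mean(reward)) / sd(reward)
  zu <- (ee_val - mean(ee_val)) / sd(ee_val)
  p <- plogis(beta_r * zr + beta_u * zu)
  data.frame(subject_id = subject_id, group = group,
             reward = reward, ee = ee_val,
             accepted = runif(n) < p)
}

test_that("choice sensitivities converge to the generative coefficients", {
  set.seed(31)
  ch <- make_choices(10000, beta_r = 1.2, beta_u = -0.8)
  sens <- fit_choice_sensitivities(ch, "exp2")
  expect_equal(sens$beta_reward_hat, 1.2, tolerance = 0.1)
  expect_equal(sens$beta_uncertainty_hat, -0.8, tolerance = 0.1)
  expect_true(sens$converged)
  expect_false(sens$separation)
})

test_that("a null reward sensitivity is covered by its confidence interval", {
  set.seed(32)
  hits <- vapply(1:40, function(i) {
    ch <- make_choices(150, beta_r = 0, beta_u = -1)
    sens <- fit_choice_sensitivities(ch, "exp2")
    abs(sens$beta_reward_hat) < 1.96 * sens$se_reward
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("deterministic threshold responding raises the separation flag", {
  set.seed(33)
  ch <- make_choices(80, beta_r = 0, beta_u = 0)
  ch$accepted <- ch$reward > median(ch$reward)
  sens <- fit_choice_sensitivities(ch, "exp2")
  expect_true(sens$separation)
  expect_true(is.finite(sens$beta_reward_hat))  # penalized fallback estimate
})

test_that("all-accept subjects are returned unconverged, not dropped", {
  set.seed(34)
  ch <- make_choices(50, beta_r = 0, beta_u = 0)
  ch$accepted <- TRUE
  sens <- fit_choice_sensitivities(ch, "exp2")
  expect_false(sens$converged)
  expect_true(is.na(sens$beta_reward_hat))
})

test_that("a perfect linear rater has calibration slope 1/sd(EE) with R2 = 1", {
  ee_val <- seq(16, 94, length.out = 20)
  conf <- data.frame(subject_id = "s01", ee = ee_val,
                     confidence = 100 - ee_val)
  # exact-fit fixture triggers summary.lm's "essentially perfect fit" note
  acc <- suppressWarnings(uncertainty_estimation_accuracy(conf))
  expect_equal(acc$slope, 1 / sd(ee_val), tolerance = 1e-10)
  expect_equal(acc$r_squared, 1, tolerance = 1e-10)

  set.seed(35)
  flat <- data.frame(subject_id = "s01", ee = ee_val,
                     confidence = 70 + rnorm(20, 0, 3))
  expect_lt(abs(uncertainty_estimation_accuracy(flat)$slope), 0.1)

  expect_error(uncertainty_estimation_accuracy(
    data.frame(subject_id = "s01", ee = rep(5, 4), confidence = 1:4)),
    "variance")
})

test_that("group contrasts use the normality gate and report effect sizes", {
  set.seed(36)
  same <- group_contrast(c(rnorm(10), rnorm(10)),
                         rep(c("control", "lesion"), each = 10))
  expect_gt(same$p_value, 0.05)

  dom <- group_contrast(c(1, 2, 3, 4, 5, 6),
                        rep(c("a", "b"), each = 3), method = "wilcoxon")
  expect_equal(dom$effect_size, -1)
  expect_identical(dom$effect_name, "cliffs_delta")

  # degenerate variance forces the rank path
  deg <- group_contrast(c(rep(1, 5), 1:5), rep(c("a", "b"), each = 5))
  expect_identical(deg$test, "wilcoxon")
})

test_that("the rank-sum statistic matches exhaustive pair counting", {
  x <- c(3.2, 1.5, 4.8, 2.2, 5.1)
  y <- c(2.8, 6.0, 4.1, 5.5, 3.9)
  ct <- group_contrast(c(x, y), rep(c("g1", "g2"), each = 5),
                       method = "wilcoxon")
  w_manual <- 0
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      w_manual <- w_manual + (x[i] > y[j]) + 0.5 * (x[i] == y[j])
    }
  }
  expect_equal(unname(ct$statistic), w_manual)
  # p-value consistent with exact enumeration over rank assignments
  exact_p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  expect_equal(ct$p_value, exact_p, tolerance = 0.05)
})

test_that("ICV adjustment is the identity at the reference mean and with zero slope", {
  rec <- data.frame(subject_id = 1:4, group = "control",
                    raw_volume = c(3000, 3100, 2900, 3050),
                    icv = c(1.4e6, 1.5e6, 1.45e6, 1.48e6))
  adj <- icv_adjust(rec, reference_slope = 0.002,
                    reference_mean_icv = 1.45e6)
  expect_equal(adj$adjusted_volume[3], rec$raw_volume[3])  # at the mean
  adj0 <- icv_adjust(rec, reference_slope = 0,
                     reference_mean_icv = 1.45e6)
  expect_equal(adj0$adjusted_volume, rec$raw_volume)
})

test_that("adjusted volumes are decorrelated from ICV on synthetic data", {
  set.seed(37)
  n <- 200
  icv <- rnorm(n, 1.5e6, 1e5)
  v <- 3000 + 0.002 * (icv - 1.5e6) + rnorm(n, 0, 30)
  rec <- data.frame(subject_id = seq_len(n), group = "control",
                    raw_volume = v, icv = icv)
  adj <- icv_adjust(rec)
  expect_lt(abs(cor(adj$adjusted_volume, adj$icv)), 0.1)
})

test_that("the robust volume regression recovers slopes and resists outliers", {
  vol <- seq(2500, 3500, length.out = 20)
  sens <- 0.002 * vol - 4
  fit <- volume_sensitivity_regression(vol, sens)
  expect_equal(fit$slope, 0.002, tolerance = 1e-8)
  expect_gt(fit$r_squared, 0.999)

  set.seed(38)
  noisy <- sens + rnorm(20, 0, 0.05)
  ols_clean <- coef(lm(noisy ~ vol))[2]
  noisy_out <- noisy
  noisy_out[7] <- noisy_out[7] + 10   # one gross outlier
  rob <- volume_sensitivity_regression(vol, noisy_out)
  expect_lt(abs(rob$slope - ols_clean) / abs(ols_clean), 0.1)

  expect_error(volume_sensitivity_regression(rep(3000, 10), rnorm(10)),
               "rank")
})

test_that("null volume-sensitivity relations are covered at nominal rate", {
  set.seed(39)
  hits <- vapply(1:40, function(i) {
    vol <- rnorm(30, 3000, 200)
    sens <- rnorm(30)
    fit <- volume_sensitivity_regression(vol, sens)
    fit$ci[1] <= 0 && fit$ci[2] >= 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("cost-sensitivity metrics separate cost-aware from cost-blind sampling", {
  # four trials per condition from two stylized subjects: one reduces
  # sampling under high cost, one does not
  trials <- expand.grid(subject_id = c("aware", "blind"),
                        reserve = c(95, 130), cost = c(1, 5),
                        rep = 1:2, stringsAsFactors = FALSE)
  trials$trial_id <- seq_len(nrow(trials))
  trials$s_taken <- ifelse(trials$subject_id == "aware" & trials$cost == 5,
                           2L, 8L)
  ee_curves <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    s <- 0:trials$s_taken[i]
    data.frame(subject_id = trials$subject_id[i],
               trial_id = trials$trial_id[i], s = s,
               ee = (85 - 8) * 0.5^s + 8)
  }))
  om <- oversampling_metrics(trials, ee_curves)
  cs <- om$cost_sensitivity
  expect_gt(cs$cost_sensitivity[cs$subject_id == "aware"],
            cs$cost_sensitivity[cs$subject_id == "blind"])
  expect_equal(cs$cost_sensitivity[cs$subject_id == "blind"], 0)
  expect_true(all(c("s_star", "deviation") %in% names(om$per_trial)))
  # identical sampling in both cost conditions gives a zero index
})
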