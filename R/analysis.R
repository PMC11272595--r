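# Estimation pipeline: per-subject logistic choice sensitivities, group
# contrasts, confidence-calibration slopes, oversampling metrics, and the
# volume-sensitivity regression with intracranial-volume adjustment.

# Firth-penalized logistic regression (Jeffreys-prior adjusted score),
# used as the fallback when the ML fit separates. Returns coefficients and
# SEs from the penalized information.
.firth_logistic <- function(X, y, max_iter = 50L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(X %*% beta))
    w <- p * (1 - p)
    XtW <- t(X * w)
    info <- XtW %*% X
    h <- rowSums((X %*% solve(info)) * (X * w))
    U <- drop(t(X) %*% (y - p + h * (0.5 - p)))
    step <- solve(info, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  p <- stats::plogis(drop(X %*% beta))
  info <- t(X * (p * (1 - p))) %*% X
  list(coef = stats::setNames(beta, colnames(X)),
       se = stats::setNames(sqrt(diag(solve(info))), colnames(X)))
}

.fit_subject_logistic <- function(dat, rhs) {
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), dat)
  y <- dat$accepted
  if (all(y) || !any(y)) {
    return(list(coef = stats::setNames(rep(NA_real_, ncol(X)), colnames(X)),
                se = stats::setNames(rep(NA_real_, ncol(X)), colnames(X)),
                converged = FALSE, separation = FALSE))
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stats::as.formula(paste("accepted ~", rhs)),
               data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || any(abs(stats::coef(fit)) > 10, na.rm = TRUE)) {
    pf <- .firth_logistic(X, as.numeric(y))
    return(list(coef = pf$coef, se = pf$se, converged = TRUE,
                separation = TRUE))
  }
  sm <- summary(fit)$coefficients
  list(coef = stats::coef(fit), se = sm[, "Std. Error"],
       converged = fit$converged, separation = FALSE)
}

.design_formula <- function(experiment) {
  switch(experiment,
    exp2 = list(rhs = "z_reward + z_uncertainty",
                terms = c(reward = "z_reward", uncertainty = "z_uncertainty")),
    exp3 = list(rhs = "z_reward + z_effort",
                terms = c(reward = "z_reward", effort = "z_effort")),
    exp4 = list(rhs = "z_reward * z_uncertainty + z_effort * z_uncertainty",
                terms = c(reward = "z_reward", uncertainty = "z_uncertainty",
                          effort = "z_effort",
                          reward_x_uncertainty = "z_reward:z_uncertainty",
                          effort_x_uncertainty = "z_uncertainty:z_effort")),
    stop("unknown experiment: ", experiment))
}

#' Per-subject choice sensitivities
#'
#' Fits, for each subject, a logistic regression of offer acceptance on
#' the design's standardized attributes: reward and EE (exp2), reward and
#' effort (exp3), or reward, effort and uncertainty presence with the
#' reward-by-uncertainty and effort-by-uncertainty interactions (exp4,
#' catch trials excluded). Coefficients are the subject's sensitivities.
#' Complete separation triggers a Firth-penalized refit and is flagged;
#' all-accept/all-reject subjects are returned unconverged.
#'
#' @param choices Choice table from [simulate_cohort()] (or conforming):
#'   columns `subject_id`, `group`, `accepted`, `reward`, and per design
#'   `ee`, `effort`, `uncertainty`, `is_catch`.
#' @param experiment `"exp2"`, `"exp3"` or `"exp4"`.
#' @return One row per subject: sensitivities `*_hat`, standard errors
#'   `se_*`, `converged`, `separation`.
#' @export
fit_choice_sensitivities <- function(choices, experiment = c("exp2", "exp3", "exp4")) {
  experiment <- match.arg(experiment)
  des <- .design_formula(experiment)
  if (experiment == "exp4" && "is_catch" %in% names(choices))
    choices <- choices[!choices$is_catch, ]
  subs <- unique(choices$subject_id)
  rows <- lapply(subs, function(sid) {
    dat <- choices[choices$subject_id == sid, ]
    dat$z_reward <- .zs(dat$reward)
    if (!is.null(dat$effort)) dat$z_effort <- .zs(dat$effort)
    dat$z_uncertainty <- switch(experiment,
      exp2 = .zs(dat$ee),
      exp3 = 0,
      exp4 = .zs(as.numeric(dat$uncertainty != "absent")))
    nlev <- vapply(strsplit(des$rhs, " [+*] ")[[1]],
                   function(v) length(unique(dat[[v]])), integer(1))
    if (any(nlev < 2))
      stop("subject ", sid, ": a predictor has fewer than 2 distinct levels")
    fit <- .fit_subject_logistic(dat, des$rhs)
    out <- data.frame(subject_id = sid,
                      group = dat$group[1], stringsAsFactors = FALSE)
    for (nm in names(des$terms)) {
      term <- des$terms[[nm]]
      out[[paste0("beta_", nm, "_hat")]] <-
        if (term %in% names(fit$coef)) unname(fit$coef[term]) else NA_real_
      out[[paste0("se_", nm)]] <-
        if (term %in% names(fit$se)) unname(fit$se[term]) else NA_real_
    }
    out$converged <- fit$converged
    out$separation <- fit$separation
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Uncertainty-estimation accuracy
#'
#' Per-subject ordinary-least-squares slope of z-scored, sign-flipped
#' confidence on EE. A positive slope means subjective uncertainty tracks
#' objective uncertainty (well-calibrated estimation).
#'
#' @param confidence Table with `subject_id`, `group` (optional), `ee`,
#'   `confidence`; at least 3 pairs and nonzero EE variance per subject.
#' @return One row per subject: `slope`, `r_squared`, `n`.
#' @export
uncertainty_estimation_accuracy <- function(confidence) {
  subs <- unique(confidence$subject_id)
  rows <- lapply(subs, function(sid) {
    dat <- confidence[confidence$subject_id == sid, ]
    if (nrow(dat) < 3) stop("subject ", sid, ": fewer than 3 ratings")
    if (stats::sd(dat$ee) == 0) stop("subject ", sid, ": zero EE variance")
    y <- .zs(-dat$confidence)
    fit <- stats::lm(y ~ dat$ee)
    data.frame(subject_id = sid,
               group = if ("group" %in% names(dat)) dat$group[1] else NA,
               slope = unname(stats::coef(fit)[2]),
               r_squared = summary(fit)$r.squared, n = nrow(dat))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Oversampling metrics from active-task logs
#'
#' For each trial, the optimal sample count s* is the argmax of the
#' expected-value curve EV(s) = R0 - s*eta_s - EE(s)*eta_e built from the
#' trial's fitted exponential EE decay (extended to `s_max` samples);
#' deviation from optimal is samples taken minus s*. Summaries are per
#' subject and reserve-by-cost cell, plus the cost-sensitivity index: the
#' drop in mean samples from the low- to the high-cost condition at high
#' reserve (the metric that separates cost-sensitive from cost-blind
#' samplers).
#'
#' @param trials Per-trial summary (`subject_id`, `trial_id`, `reserve`,
#'   `cost`, `s_taken`), as from [simulate_cohort()].
#' @param ee_curves Long EE table (`subject_id`, `trial_id`, `s`, `ee`).
#' @param s_max Maximum sample count for the EV curves.
#' @param eta_e Error cost in credits per pixel.
#' @return A list: `per_trial` (with `s_star` and `deviation`), `cells`
#'   (mean deviation and samples per subject x condition; missing cells
#'   reported as NA), `cost_sensitivity` (per subject).
#' @export
oversampling_metrics <- function(trials, ee_curves, s_max = 40L,
                                 eta_e = cq_design$error_cost) {
  per_trial <- trials
  per_trial$s_star <- NA_integer_
  for (sid in unique(trials$subject_id)) {
    idx <- which(trials$subject_id == sid)
    curves <- lapply(trials$trial_id[idx], function(tid) {
      ee_curves$ee[ee_curves$subject_id == sid & ee_curves$trial_id == tid]
    })
    names(curves) <- as.character(trials$trial_id[idx])
    usable <- vapply(curves, length, integer(1)) >= 2L
    if (!any(usable)) next
    fits <- suppressWarnings(fit_extraction_rate(curves[usable]))
    for (j in seq_len(nrow(fits))) {
      k <- idx[match(fits$trial_id[j], as.character(trials$trial_id[idx]))]
      # EV uses the trial's realized EE while observed, extended past the
      # stopping point by the fitted decay anchored at the last realized
      # value (keeps the optimality analysis consistent with the trial's
      # own dynamics; the shared-start fit is only the extrapolation rate)
      obs <- curves[[as.character(trials$trial_id[k])]]
      n_obs <- length(obs)
      pred <- obs
      if (s_max + 1L > n_obs) {
        gap <- max(obs[n_obs] - fits$ee_inf[j], 0)
        tail_k <- seq_len(s_max + 1L - n_obs)
        pred <- c(obs, fits$ee_inf[j] + gap * (1 - fits$alpha[j])^tail_k)
      }
      econ <- trial_economics(trials$reserve[k], trials$cost[k],
                              eta_e = eta_e)
      ev <- expected_value_curve(econ, pred)
      per_trial$s_star[k] <- optimal_samples(ev)$s_star
    }
  }
  per_trial$deviation <- deviation_from_optimal(per_trial$s_taken,
                                                per_trial$s_star)
  cells <- expand.grid(subject_id = unique(trials$subject_id),
                       reserve = sort(unique(trials$reserve)),
                       cost = sort(unique(trials$cost)),
                       stringsAsFactors = FALSE)
  cells$mean_deviation <- NA_real_
  cells$mean_samples <- NA_real_
  for (j in seq_len(nrow(cells))) {
    sel <- per_trial$subject_id == cells$subject_id[j] &
      per_trial$reserve == cells$reserve[j] & per_trial$cost == cells$cost[j]
    if (any(sel)) {
      cells$mean_deviation[j] <- mean(per_trial$deviation[sel], na.rm = TRUE)
      cells$mean_samples[j] <- mean(per_trial$s_taken[sel])
    }
  }
  hi_r <- max(trials$reserve); lo_c <- min(trials$cost); hi_c <- max(trials$cost)
  cs <- vapply(unique(trials$subject_id), function(sid) {
    a <- cells$mean_samples[cells$subject_id == sid &
                              cells$reserve == hi_r & cells$cost == lo_c]
    b <- cells$mean_samples[cells$subject_id == sid &
                              cells$reserve == hi_r & cells$cost == hi_c]
    if (length(a) && length(b)) a - b else NA_real_
  }, numeric(1))
  list(per_trial = per_trial, cells = cells,
       cost_sensitivity = data.frame(subject_id = unique(trials$subject_id),
                                     cost_sensitivity = cs,
                                     row.names = NULL))
}

#' Cliff's delta effect size
#'
#' The dominance statistic mean(sign(x_i - y_j)) over all cross-group
#' pairs; -1 when every x is below every y, +1 for the reverse.
#'
#' @param x,y Numeric vectors.
#' @return Delta in [-1, 1].
#' @export
cliffs_delta <- function(x, y) {
  mean(sign(outer(x, y, `-`)))
}

#' Two-group contrast with effect size
#'
#' Compares a per-subject metric between two groups with a two-sided
#' Student's t-test (Cohen's d) when both groups pass a Shapiro-Wilk
#' normality check at alpha = 0.05, otherwise a Wilcoxon rank-sum test
#' (Cliff's delta). Degenerate within-group variance forces the rank path.
#'
#' @param values Numeric per-subject metric.
#' @param groups Factor/character of the same length; the first level is
#'   the reference in the effect-size sign.
#' @param metric Label carried into the result.
#' @param method `"auto"` (normality gate), `"t"`, or `"wilcoxon"`.
#' @return A `cq_contrast` data.frame row: group means/medians, test name,
#'   statistic, p-value, effect size.
#' @export
group_contrast <- function(values, groups, metric = "metric",
                           method = c("auto", "t", "wilcoxon")) {
  method <- match.arg(method)
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2)
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop(">= 2 subjects per group required")
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (method == "auto") {
    normal <- !degenerate &&
      (length(x) < 3 || stats::shapiro.test(x)$p.value > 0.05) &&
      (length(y) < 3 || stats::shapiro.test(y)$p.value > 0.05)
    method <- if (normal) "t" else "wilcoxon"
  }
  if (method == "t" && degenerate) method <- "wilcoxon"
  if (method == "t") {
    tt <- stats::t.test(x, y)
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    eff <- if (sp == 0) 0 else (mean(x) - mean(y)) / sp
    eff_name <- "cohens_d"
    stat <- unname(tt$statistic); p <- tt$p.value; test <- "t"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    eff <- cliffs_delta(x, y)
    eff_name <- "cliffs_delta"
    stat <- unname(wt$statistic); p <- wt$p.value; test <- "wilcoxon"
  }
  structure(data.frame(metric = metric,
                       group1 = levels(groups)[1], group2 = levels(groups)[2],
                       mean1 = mean(x), mean2 = mean(y),
                       median1 = stats::median(x), median2 = stats::median(y),
                       n1 = length(x), n2 = length(y),
                       test = test, statistic = stat, p_value = p,
                       effect_size = eff, effect_name = eff_name,
                       stringsAsFactors = FALSE),
            class = c("cq_contrast", "data.frame"))
}

#' Adjust regional volumes for intracranial volume
#'
#' Vadj = V - beta * (ICV - mean ICV), with the slope beta and reference
#' mean taken from a designated reference (control) sample or supplied
#' directly.
#'
#' @param records Table with `raw_volume` and `icv` (mm^3), optionally
#'   `group`.
#' @param reference_slope,reference_mean_icv Optional fixed regression
#'   slope of volume on ICV and reference mean ICV; when NULL both are
#'   estimated from `reference` rows.
#' @param reference Logical vector selecting the reference sample
#'   (default: rows with `group == "control"` when present, else all).
#' @return `records` with an `adjusted_volume` column; the slope and mean
#'   used are attached as attributes.
#' @export
icv_adjust <- function(records, reference_slope = NULL,
                       reference_mean_icv = NULL, reference = NULL) {
  stopifnot(all(records$raw_volume > 0), all(records$icv > 0))
  if (is.null(reference))
    reference <- if ("group" %in% names(records))
      records$group == "control" else rep(TRUE, nrow(records))
  if (is.null(reference_slope))
    reference_slope <- unname(stats::coef(
      stats::lm(raw_volume ~ icv, data = records[reference, ]))[2])
  if (is.null(reference_mean_icv))
    reference_mean_icv <- mean(records$icv[reference])
  records$adjusted_volume <- records$raw_volume -
    reference_slope * (records$icv - reference_mean_icv)
  attr(records, "reference_slope") <- reference_slope
  attr(records, "reference_mean_icv") <- reference_mean_icv
  records
}

#' Robust volume-sensitivity regression
#'
#' Regresses a behavioural sensitivity on (adjusted) volume by iteratively
#' reweighted least squares with Tukey bisquare weights (tuning constant
#' 4.685), optionally with covariates.
#'
#' @param volumes Numeric adjusted volumes.
#' @param sensitivities Numeric per-subject sensitivities (response).
#' @param covariates Optional data.frame of extra predictors (e.g. age).
#' @return A list: `slope`, `se`, `ci` (95%), `r_squared` (weighted),
#'   `n`, and the `MASS::rlm` fit.
#' @export
volume_sensitivity_regression <- function(volumes, sensitivities,
                                          covariates = NULL) {
  ok <- is.finite(volumes) & is.finite(sensitivities)
  dat <- data.frame(sensitivity = sensitivities[ok], volume = volumes[ok])
  if (!is.null(covariates)) dat <- cbind(dat, covariates[ok, , drop = FALSE])
  if (nrow(dat) < 5) stop(">= 5 paired observations required")
  X <- stats::model.matrix(sensitivity ~ ., dat)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  fit <- MASS::rlm(sensitivity ~ ., data = dat, psi = MASS::psi.bisquare,
                   c = 4.685, maxit = 100)
  sm <- summary(fit)$coefficients
  slope <- sm["volume", "Value"]; se <- sm["volume", "Std. Error"]
  tcrit <- stats::qt(0.975, nrow(dat) - ncol(X))
  w <- fit$w
  ybar <- sum(w * dat$sensitivity) / sum(w)
  r2 <- 1 - sum(w * stats::residuals(fit)^2) /
    sum(w * (dat$sensitivity - ybar)^2)
  list(slope = slope, se = se, ci = c(slope - tcrit * se, slope + tcrit * se),
       r_squared = r2, n = nrow(dat), fit = fit)
}
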