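# Synthetic participants: logistic accept/reject choices over standardized
# offer attributes, an information-greedy active-sampling policy with a
# subjective stopping rule, and a linear confidence mapping.

#' Generative parameters of a synthetic participant
#'
#' @param group `"control"` or `"lesion"`. The lesion phenotype keeps
#'   uncertainty sensitivity intact but attenuates reward and effort
#'   sensitivity when uncertainty is present (`gamma_context` < 1) and
#'   under-weights the sampling cost in the active task (`w_cost` << 1).
#' @param beta0 Choice intercept (log-odds of acceptance at average offer).
#' @param beta_reward Acceptance weight per standardized reward unit.
#' @param beta_uncertainty Weight per standardized EE unit (negative:
#'   more uncertainty, fewer acceptances).
#' @param beta_effort Weight per standardized effort unit (negative).
#' @param gamma_context Multiplicative attenuation of `beta_reward` and
#'   `beta_effort` when uncertainty is present, in (0, 1].
#' @param w_cost Subjective weight on the sampling cost in the active
#'   stopping rule (1 = veridical, 0 = cost-blind).
#' @param sampling_jitter SD in pixels of Gaussian noise around the
#'   information-optimal sample location.
#' @param isi_base,isi_slope Seconds; the inter-sampling interval is
#'   `isi_base + isi_slope * 10 / (10 + sampling_jitter)` (lognormal
#'   multiplicative noise), so sloppier samplers are faster - the speed
#'   axis of the speed-efficiency trade-off.
#' @param placement_noise SD in pixels of motor noise on the final
#'   placement.
#' @param conf_intercept,conf_slope,conf_noise Linear mapping from EE to a
#'   0-100 confidence rating (slope <= 0: higher EE, lower confidence).
#' @param rt_meanlog,rt_sdlog Lognormal response-time parameters (s).
#' @return A `cq_agent`.
#' @export
agent_params <- function(group = c("control", "lesion"),
                         beta0 = 0, beta_reward = 1.5,
                         beta_uncertainty = -1.5, beta_effort = -1.5,
                         gamma_context = if (group == "lesion") 0.4 else 1,
                         w_cost = if (group == "lesion") 0.1 else 1,
                         sampling_jitter = 20,
                         isi_base = 0.4, isi_slope = 0.8,
                         placement_noise = 5,
                         conf_intercept = 95, conf_slope = -0.85,
                         conf_noise = 8,
                         rt_meanlog = 0.4, rt_sdlog = 0.3) {
  group <- match.arg(group)
  stopifnot(gamma_context > 0, gamma_context <= 1, w_cost >= 0,
            sampling_jitter >= 0, conf_slope <= 0, conf_noise >= 0)
  structure(list(group = group, beta0 = beta0, beta_reward = beta_reward,
                 beta_uncertainty = beta_uncertainty,
                 beta_effort = beta_effort, gamma_context = gamma_context,
                 w_cost = w_cost, sampling_jitter = sampling_jitter,
                 isi_base = isi_base, isi_slope = isi_slope,
                 placement_noise = placement_noise,
                 conf_intercept = conf_intercept, conf_slope = conf_slope,
                 conf_noise = conf_noise, rt_meanlog = rt_meanlog,
                 rt_sdlog = rt_sdlog),
            class = "cq_agent")
}

#' One (or several) passive accept/reject choices
#'
#' P(accept) = logistic(beta0 + bR * z_reward + beta_uncertainty * z_unc +
#' bE * z_effort), where bR and bE are attenuated by `gamma_context` on
#' trials with uncertainty present. Predictors are standardized within the
#' experiment's design before being passed in.
#'
#' @param agent A `cq_agent`.
#' @param z_reward,z_uncertainty,z_effort Standardized offer attributes
#'   (vectors of common length; use 0 for attributes absent from a design).
#' @param uncertainty_present Logical vector: does the offer carry
#'   uncertainty? Controls the context attenuation.
#' @return A data.frame with `p_accept`, `accepted`, `response_time`.
#' @export
passive_choice <- function(agent, z_reward = 0, z_uncertainty = 0,
                           z_effort = 0, uncertainty_present = TRUE) {
  stopifnot(inherits(agent, "cq_agent"))
  n <- max(length(z_reward), length(z_uncertainty), length(z_effort),
           length(uncertainty_present))
  z_reward <- rep_len(z_reward, n)
  z_uncertainty <- rep_len(z_uncertainty, n)
  z_effort <- rep_len(z_effort, n)
  uncertainty_present <- rep_len(uncertainty_present, n)
  atten <- ifelse(uncertainty_present, agent$gamma_context, 1)
  lp <- agent$beta0 +
    agent$beta_reward * atten * z_reward +
    agent$beta_uncertainty * z_uncertainty +
    agent$beta_effort * atten * z_effort
  p <- stats::plogis(lp)
  data.frame(p_accept = p,
             accepted = stats::runif(n) < p,
             response_time = stats::rlnorm(n, agent$rt_meanlog,
                                           agent$rt_sdlog))
}

#' Confidence rating for a stimulus
#'
#' A linear read-out of EE clipped to the 0-100 scale:
#' `clip(conf_intercept + conf_slope * EE + N(0, conf_noise), 0, 100)`.
#'
#' @param agent A `cq_agent`.
#' @param stimulus A `cq_stimulus`, a `cq_uncertainty`, or a numeric EE.
#' @return Rating(s) in [0, 100].
#' @export
confidence_report <- function(agent, stimulus) {
  stopifnot(inherits(agent, "cq_agent"))
  ee_val <- if (inherits(stimulus, "cq_stimulus")) stimulus$achieved_ee
            else if (inherits(stimulus, "cq_uncertainty")) stimulus$ee
            else as.numeric(stimulus)
  raw <- agent$conf_intercept + agent$conf_slope * ee_val +
    stats::rnorm(length(ee_val), 0, agent$conf_noise)
  pmin(pmax(raw, 0), 100)
}

# Expected posterior EE after observing at point q: mass-weighted average
# of the EE of the inside-branch and outside-branch posteriors.
.expected_ee_after <- function(cx, cy, w, q, r2) {
  d2 <- (cx - q[1])^2 + (cy - q[2])^2
  kin <- d2 <= r2
  p_in <- sum(w[kin])
  ee_branch <- function(keep, mass) {
    if (mass <= 0) return(0)
    wx <- w[keep] / mass
    bx <- cx[keep]; by <- cy[keep]
    mx <- sum(wx * bx); my <- sum(wx * by)
    sum(wx * sqrt((bx - mx)^2 + (by - my)^2))
  }
  p_in * ee_branch(kin, p_in) + (1 - p_in) * ee_branch(!kin, 1 - p_in)
}

.sample_lattice <- function(space, nx = 16L, ny = 12L) {
  xs <- seq(space$width / (2 * nx), space$width, length.out = nx)
  ys <- seq(space$height / (2 * ny), space$height, length.out = ny)
  cbind(rep(xs, times = ny), rep(ys, each = nx))
}

.snap_to_grid <- function(p, space) {
  r <- space$circle_radius; st <- space$grid_step
  snap1 <- function(v, lo, hi) min(max(lo + round((v - lo) / st) * st, lo), hi)
  c(snap1(p[1], r, r + floor((space$width - 2 * r) / st) * st),
    snap1(p[2], r, r + floor((space$height - 2 * r) / st) * st))
}

.clamp_to_space <- function(p, space) {
  c(min(max(p[1], 0), space$width), min(max(p[2], 0), space$height))
}

#' Simulate one active-sampling trial
#'
#' The agent starts from the initially displayed inside dot, repeatedly
#' picks the approximately information-optimal next sample (the lattice
#' point minimizing the expected posterior EE after one observation) plus
#' Gaussian jitter, and stops when the subjective one-step value of
#' information, `deltaEE * eta_e - w_cost * eta_s`, is no longer positive
#' or the time budget is exhausted. The final placement is the posterior
#' centroid plus motor noise.
#'
#' @param agent A `cq_agent`.
#' @param econ A `cq_econ`.
#' @param space A `cq_space`.
#' @param true_center Numeric `(x, y)`; snapped to the candidate grid so
#'   simulated observations are exactly consistent with the posterior.
#' @param time_budget Sampling window in seconds (task value: 18).
#' @param lattice_nx,lattice_ny Resolution of the candidate-sample lattice.
#' @param max_samples Hard cap on acquired samples.
#' @return A `cq_trajectory`: `samples` (acquired observations with
#'   timestamps), `displayed` (the initial dot), `ee_per_sample` (length
#'   samples + 1, starting at the displayed-dot state), `placement`,
#'   `placement_error`, `s_taken`, `true_center`, `score`.
#' @export
active_sampling_episode <- function(agent, econ, space, true_center,
                                    time_budget = 18,
                                    lattice_nx = 16L, lattice_ny = 12L,
                                    max_samples = 40L) {
  stopifnot(inherits(agent, "cq_agent"), inherits(econ, "cq_econ"),
            inherits(space, "cq_space"))
  true_center <- .snap_to_grid(true_center, space)
  r <- space$circle_radius; r2 <- r^2
  belief <- init_posterior(space)
  # initially displayed inside dot
  disp <- .runif_disk(true_center, r)
  disp <- .clamp_to_space(disp, space)
  obs0 <- simulate_observation(true_center, disp, space, timestamp = 0)
  belief <- update_posterior(belief, obs0$x, obs0$y, obs0$label, 0)
  lattice <- .sample_lattice(space, lattice_nx, lattice_ny)
  ee_now <- ee(belief)$ee
  ee_track <- ee_now
  samples <- list()
  t_now <- 0
  isi_mean <- agent$isi_base +
    agent$isi_slope * 10 / (10 + agent$sampling_jitter)
  theta <- seq(0, 2 * pi, length.out = 9L)[-9L]
  repeat {
    if (length(samples) >= max_samples) break
    # candidate next samples: the coarse lattice plus adaptive points whose
    # radius-r observation circle crosses the current support at varying
    # offsets (without these, a small sliver support cannot be bisected
    # finely and late-stage information gains stall below the true optimum)
    ctr <- c(sum(belief$w * belief$cx), sum(belief$w * belief$cy))
    ring <- do.call(rbind, lapply(c(-0.5, 0, 0.5) * ee_now, function(d)
      cbind(ctr[1] + (r + d) * cos(theta), ctr[2] + (r + d) * sin(theta))))
    ring[, 1] <- pmin(pmax(ring[, 1], 0), space$width)
    ring[, 2] <- pmin(pmax(ring[, 2], 0), space$height)
    cand <- rbind(lattice, ring)
    exp_ee <- apply(cand, 1L, function(q)
      .expected_ee_after(belief$cx, belief$cy, belief$w, q, r2))
    best_i <- which.min(exp_ee)
    delta_ee <- ee_now - exp_ee[best_i]
    if (delta_ee * econ$eta_e - agent$w_cost * econ$eta_s <= 0) break
    isi <- isi_mean * stats::rlnorm(1, 0, 0.1)
    if (t_now + isi > time_budget) break
    t_now <- t_now + isi
    pt <- .clamp_to_space(cand[best_i, ] +
                            stats::rnorm(2, 0, agent$sampling_jitter), space)
    obs <- simulate_observation(true_center, pt, space, timestamp = t_now)
    belief <- update_posterior(belief, obs$x, obs$y, obs$label, t_now)
    samples[[length(samples) + 1L]] <- obs
    ee_now <- ee(belief)$ee
    ee_track <- c(ee_track, ee_now)
  }
  samples <- if (length(samples)) do.call(rbind, samples)
             else obs0[0, , drop = FALSE]
  placement <- best_placement(belief) +
    stats::rnorm(2, 0, agent$placement_noise)
  err <- localization_error(placement, true_center)
  structure(list(samples = samples, displayed = obs0,
                 ee_per_sample = ee_track,
                 placement = placement, placement_error = err,
                 s_taken = nrow(samples), true_center = true_center,
                 score = trial_score(econ, nrow(samples), err),
                 econ = econ),
            class = "cq_trajectory")
}

#' @export
print.cq_trajectory <- function(x, ...) {
  cat(sprintf("<cq_trajectory: %d samples, final EE %.1f px, error %.1f px, score %.1f>\n",
              x$s_taken, utils::tail(x$ee_per_sample, 1),
              x$placement_error, x$score))
  invisible(x)
}

#' Cohort configuration
#'
#' Group-level means are the `agent_params()` arguments; `sds` gives the
#' between-subject SD of each listed parameter (untouched parameters are
#' identical across a group's agents). `gamma_context` and `w_cost` draws
#' are truncated into their admissible ranges.
#'
#' @param n_per_group Subjects per group (study: 19 + 19 in exps 1-2).
#' @param control,lesion Named lists overriding [agent_params()] defaults.
#' @param sds Named list of between-subject SDs (default: 0.3 on the three
#'   choice sensitivities).
#' @param seed Master seed; per-subject seeds are derived from it by a
#'   fixed counter scheme.
#' @return A `cq_cohort_config`.
#' @export
cohort_config <- function(n_per_group = 19L, control = list(),
                          lesion = list(),
                          sds = list(beta_reward = 0.3,
                                     beta_uncertainty = 0.3,
                                     beta_effort = 0.3),
                          seed = 1L) {
  stopifnot(n_per_group >= 1)
  stopifnot(all(unlist(sds) >= 0))
  structure(list(n_per_group = as.integer(n_per_group),
                 control = control, lesion = lesion, sds = sds,
                 seed = as.integer(seed)),
            class = "cq_cohort_config")
}

.subject_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + i * 9973) %% 2147483629)
}

.draw_agent <- function(group, overrides, sds) {
  base <- do.call(agent_params, c(list(group = group), overrides))
  for (nm in names(sds)) {
    if (!nm %in% names(base) || !is.numeric(base[[nm]])) next
    v <- stats::rnorm(1, base[[nm]], sds[[nm]])
    if (nm == "gamma_context") v <- min(max(v, 1e-3), 1)
    if (nm %in% c("w_cost", "sampling_jitter", "conf_noise")) v <- max(v, 0)
    if (nm == "conf_slope") v <- min(v, 0)
    base[[nm]] <- v
  }
  base
}

.truth_row <- function(subject_id, agent) {
  data.frame(subject_id = subject_id, group = agent$group,
             beta0 = agent$beta0, beta_reward = agent$beta_reward,
             beta_uncertainty = agent$beta_uncertainty,
             beta_effort = agent$beta_effort,
             gamma_context = agent$gamma_context, w_cost = agent$w_cost,
             sampling_jitter = agent$sampling_jitter,
             conf_intercept = agent$conf_intercept,
             conf_slope = agent$conf_slope)
}

# z-score a vector; all-constant vectors map to 0.
.zs <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Realize per-trial EE and standardized predictors for a passive schedule.
.prepare_passive_design <- function(schedule, experiment) {
  sch <- schedule
  sch$ee <- ifelse(is.na(sch$ee_lo), 0,
                   stats::runif(nrow(sch), sch$ee_lo, sch$ee_hi))
  sch$uncertainty_present <-
    !is.na(sch$uncertainty) & sch$uncertainty != "absent"
  sch$z_reward <- .zs(sch$reward)
  sch$z_effort <- if (all(is.na(sch$effort))) 0 else .zs(sch$effort)
  sch$z_uncertainty <- switch(experiment,
    exp2 = .zs(sch$ee),
    exp3 = 0,
    exp4 = .zs(as.numeric(sch$uncertainty_present)),
    .zs(sch$ee))
  sch
}

#' Simulate a full cohort on one experiment
#'
#' Draws `n_per_group` agents per group from the configured parameter
#' distributions, gives each subject a fresh seed-derived schedule, and
#' simulates the experiment. Passive experiments (exp2-exp4) yield choice
#' and confidence tables; the active experiment (exp1) yields sampling
#' trajectories. A ground-truth parameter table is always emitted for
#' parameter-recovery testing.
#'
#' @param config A `cq_cohort_config`.
#' @param experiment `"exp1"`, `"exp2"`, `"exp3"` or `"exp4"`.
#' @param space A `cq_space` (exp1 only).
#' @param n_trials Optional cap on trials per subject (exp1 only; useful
#'   for keeping simulation studies small).
#' @return A list of data.frames: always `truth`; for passive experiments
#'   `choices` and (exp2/exp4) `confidence`; for exp1 `trials` (per-trial
#'   summaries), `ee_curves` (long EE-by-sample), `samples` (long sample
#'   events), and `trajectories` (nested list).
#' @export
simulate_cohort <- function(config, experiment = c("exp2", "exp1", "exp3", "exp4"),
                            space = search_space(), n_trials = NULL) {
  stopifnot(inherits(config, "cq_cohort_config"))
  experiment <- match.arg(experiment)
  n <- config$n_per_group
  groups <- rep(c("control", "lesion"), each = n)
  truth <- list(); choices <- list(); confidence <- list()
  trials <- list(); ee_curves <- list(); sample_rows <- list()
  trajectories <- list()
  for (i in seq_along(groups)) {
    sid <- sprintf("s%02d", i)
    set.seed(.subject_seed(config$seed, i))
    agent <- .draw_agent(groups[i],
                         if (groups[i] == "control") config$control
                         else config$lesion,
                         config$sds)
    truth[[i]] <- .truth_row(sid, agent)
    sched_seed <- .subject_seed(config$seed, i + 100000)
    if (experiment == "exp1") {
      sch <- exp1_schedule(sched_seed)
      if (!is.null(n_trials)) sch <- sch[seq_len(min(n_trials, nrow(sch))), ]
      set.seed(.subject_seed(config$seed, i + 200000))
      subj_traj <- vector("list", nrow(sch))
      for (k in seq_len(nrow(sch))) {
        econ <- trial_economics(sch$reserve[k], sch$cost[k])
        ctr <- .random_admissible_center(space)
        tr <- active_sampling_episode(agent, econ, space, ctr)
        subj_traj[[k]] <- tr
        trials[[length(trials) + 1L]] <- data.frame(
          subject_id = sid, group = agent$group, trial_id = sch$trial_id[k],
          reserve = sch$reserve[k], cost = sch$cost[k],
          s_taken = tr$s_taken, placement_error = tr$placement_error,
          score = tr$score,
          mean_isi = inter_sampling_intervals(tr)$mean)
        ee_curves[[length(ee_curves) + 1L]] <- data.frame(
          subject_id = sid, trial_id = sch$trial_id[k],
          s = seq_along(tr$ee_per_sample) - 1L, ee = tr$ee_per_sample)
        if (tr$s_taken > 0)
          sample_rows[[length(sample_rows) + 1L]] <-
            cbind(subject_id = sid, trial_id = sch$trial_id[k], tr$samples)
      }
      trajectories[[sid]] <- subj_traj
    } else {
      sch <- switch(experiment, exp2 = exp2_schedule(sched_seed),
                    exp3 = exp3_schedule(sched_seed),
                    exp4 = exp4_schedule(sched_seed))
      set.seed(.subject_seed(config$seed, i + 200000))
      des <- .prepare_passive_design(sch, experiment)
      ch <- passive_choice(agent, des$z_reward, des$z_uncertainty,
                           des$z_effort, des$uncertainty_present)
      choices[[i]] <- cbind(subject_id = sid, group = agent$group,
                            des[, c("trial_id", "block", "reward", "effort",
                                    "uncertainty", "ee", "is_catch")],
                            ch)
      if (experiment %in% c("exp2", "exp4")) {
        conf_idx <- if (experiment == "exp2") seq_len(nrow(des))
                    else which(des$uncertainty_present)
        confidence[[i]] <- data.frame(
          subject_id = sid, group = agent$group,
          trial_id = des$trial_id[conf_idx], ee = des$ee[conf_idx],
          confidence = confidence_report(agent, des$ee[conf_idx]))
      }
    }
  }
  out <- list(truth = do.call(rbind, truth))
  if (experiment == "exp1") {
    out$trials <- do.call(rbind, trials)
    out$ee_curves <- do.call(rbind, ee_curves)
    out$samples <- if (length(sample_rows)) do.call(rbind, sample_rows)
                   else NULL
    out$trajectories <- trajectories
  } else {
    out$choices <- do.call(rbind, choices)
    if (length(confidence)) out$confidence <- do.call(rbind, confidence)
  }
  rownames(out$truth) <- NULL
  out
}
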