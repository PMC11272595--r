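# Trial schedules and stimulus generation for the four experiments:
#   exp1 — active sampling, 2 reserve x 2 cost blocks;
#   exp2 — passive accept/reject, reward x uncertainty (EE bands);
#   exp3 — accept/reject, reward (apples) x effort (% MVC);
#   exp4 — accept/reject, reward x effort x uncertainty present/absent,
#          plus out-of-band catch trials.

#' Experiment design constants
#'
#' The printed factorial levels of the four experiments: initial reserves
#' and sampling costs (exp1), reward levels in credits (exp2/exp4), reward
#' levels in apples (exp3), effort levels in % MVC, the five exp2 EE bands
#' in pixels, the exp4 present-uncertainty band, and the catch-trial EE
#' cutoffs (low < 23 px with floor 17.9, high > 91 px with ceiling 93.3).
#'
#' @format A named list.
#' @export
cq_design <- list(
  exp1_reserve = c(low = 95, high = 130),
  exp1_cost = c(low = 1, high = 5),
  exp1_trials_per_condition = 15L,
  exp2_rewards = c(40, 65, 90, 115),
  exp2_ee_bands = matrix(c(16.3, 24.4,
                           27.1, 38.9,
                           57.5, 58.9,
                           73.33, 74.18,
                           91.9, 93.3),
                         ncol = 2, byrow = TRUE,
                         dimnames = list(NULL, c("lo", "hi"))),
  exp3_rewards = c(1, 4, 7, 10, 13),
  effort_levels = c(16, 32, 48, 64, 80),
  exp4_rewards = c(40, 65, 90, 115),
  exp4_present_band = c(lo = 31.8, hi = 73.95),
  exp4_catch_low = c(lo = 17.9, hi = 23),
  exp4_catch_high = c(lo = 91, hi = 93.3),
  error_cost = 1.2
)

# Uniform point in the disk of radius rho around centre (x, y).
.runif_disk <- function(center, rho) {
  a <- stats::runif(1, 0, 2 * pi)
  d <- rho * sqrt(stats::runif(1))
  center + d * c(cos(a), sin(a))
}

.in_space <- function(p, space) {
  p[1] >= 0 && p[1] <= space$width && p[2] >= 0 && p[2] <= space$height
}

.random_admissible_center <- function(space) {
  r <- space$circle_radius
  c(stats::runif(1, r, space$width - r), stats::runif(1, r, space$height - r))
}

#' Expected error of a dot configuration
#'
#' Builds the posterior over circle centres implied by a set of labelled
#' dots (uniform prior, hard inside/outside constraints) and returns its EE
#' and centroid. This is the quantity a stimulus "shows" an observer.
#'
#' @param dots data.frame with columns `x`, `y`, `label`.
#' @param space A `cq_space`.
#' @return A `cq_uncertainty` (see [ee()]).
#' @export
stimulus_ee <- function(dots, space) {
  g <- .candidate_grid(space)
  r2 <- space$circle_radius^2
  keep <- rep(TRUE, length(g$cx))
  # uniform prior + hard constraints: the posterior is uniform over the
  # surviving candidate set, so constraints can be applied in one pass
  # (identical to sequential update_posterior() calls)
  for (i in seq_len(nrow(dots))) {
    d2 <- (g$cx - dots$x[i])^2 + (g$cy - dots$y[i])^2
    keep <- keep & (if (dots$label[i] == "inside") d2 <= r2 else d2 > r2)
    if (!any(keep))
      stop("dot configuration inconsistent: empty posterior at dot ", i)
  }
  cx <- g$cx[keep]; cy <- g$cy[keep]
  ctr <- c(x = mean(cx), y = mean(cy))
  structure(list(ee = mean(sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2)),
                 centroid = ctr, support_size = length(cx)),
            class = "cq_uncertainty")
}

# One proposal draw. The four inside dots cluster (spread u^2 * r) around
# a locus p; the true centre is drawn within the region consistent with
# them, so it need not coincide with the cluster. Each outside dot is
# either a "carver" placed near the cluster — which removes the middle of
# the posterior support and produces ring/sliver geometries with high EE —
# or spread uniformly over the space. Mixing over the cluster spread u and
# the carver fraction v covers the feasible EE range from a few pixels up
# to ~130.
.propose_stimulus <- function(space, regime = c("generic", "high")) {
  regime <- match.arg(regime)
  r <- space$circle_radius
  if (regime == "high") {
    # tight cluster, true centre near the rim of the consistent region,
    # carver-dominated outside dots: sliver/ring supports with large EE
    u <- stats::runif(1, 0, 0.25)
    v <- stats::runif(1, 0.5, 1)
  } else {
    u <- stats::runif(1)
    v <- stats::runif(1)
  }
  rho <- u^2 * r
  repeat {
    p <- c(stats::runif(1, r, space$width - r),
           stats::runif(1, r, space$height - r))
    ctr <- if (regime == "high")
      p + stats::runif(1, 0.85, 1) * (r - rho) *
        (function(a) c(cos(a), sin(a)))(stats::runif(1, 0, 2 * pi))
    else .runif_disk(p, r - rho)
    if (ctr[1] >= r && ctr[1] <= space$width - r &&
        ctr[2] >= r && ctr[2] <= space$height - r) break
  }
  inside <- t(vapply(1:4, function(i) {
    repeat {
      q <- .runif_disk(p, rho)
      if (.in_space(q, space)) return(q)
    }
  }, numeric(2)))
  outside <- t(vapply(1:4, function(i) {
    for (try in 1:200) {
      if (stats::runif(1) < v) {
        q <- .runif_disk(p, 2 * r * stats::runif(1))
      } else {
        q <- c(stats::runif(1, 0, space$width),
               stats::runif(1, 0, space$height))
      }
      if (.in_space(q, space) && sum((q - ctr)^2) > r^2) return(q)
    }
    # fall back to a far corner point guaranteed outside the circle
    q <- c(ifelse(ctr[1] > space$width / 2, 0, space$width),
           ifelse(ctr[2] > space$height / 2, 0, space$height))
    q
  }, numeric(2)))
  list(true_center = ctr,
       dots = data.frame(x = c(inside[, 1], outside[, 1]),
                         y = c(inside[, 2], outside[, 2]),
                         label = rep(c("inside", "outside"), each = 4)))
}

#' Generate an 8-dot passive stimulus in a target EE band
#'
#' Rejection sampling: draw a true centre, four inside dots and four
#' outside dots, compute the configuration's EE from the dots alone, and
#' accept when it falls inside `band`. The proposal mixes cluster
#' tightness of the inside dots and rim-adjacency of the outside dots so
#' the whole feasible EE range is reachable.
#'
#' @param space A `cq_space`.
#' @param band Numeric `(lo, hi)` target EE interval in pixels.
#' @param seed Optional integer seed (recorded in the result).
#' @param max_attempts Attempts before giving up (default 10000).
#' @return A `cq_stimulus`: `dots` (8 rows, 4 inside + 4 outside),
#'   `achieved_ee`, `ee_band`, `true_center`, `seed`.
#' @export
generate_passive_stimulus <- function(space, band, seed = NULL,
                                      max_attempts = 10000L) {
  stopifnot(inherits(space, "cq_space"), length(band) == 2, band[1] < band[2])
  if (band[1] < 0) stop("band must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  evals <- 0L
  while (evals < max_attempts) {
    regime <- if (band[1] >= 80 && stats::runif(1) < 0.8) "high" else "generic"
    prop <- .propose_stimulus(space, regime)
    est <- tryCatch(stimulus_ee(prop$dots, space), error = function(e) NULL)
    evals <- evals + 1L
    if (is.null(est)) next
    if (est$ee >= band[1] && est$ee <= band[2]) {
      return(structure(list(dots = prop$dots, achieved_ee = est$ee,
                            ee_band = band, true_center = prop$true_center,
                            seed = seed, attempts = evals),
                       class = "cq_stimulus"))
    }
    tuned <- .tune_probe_dot(prop, band, space)
    evals <- evals + tuned$evals
    if (!is.null(tuned$dots)) {
      return(structure(list(dots = tuned$dots, achieved_ee = tuned$ee,
                            ee_band = band, true_center = prop$true_center,
                            seed = seed, attempts = evals),
                       class = "cq_stimulus"))
    }
  }
  stop("no stimulus found in EE band [", band[1], ", ", band[2], "] after ",
       max_attempts, " attempts: band may be infeasible for this space")
}

# Refine a missed proposal into the target band by sliding one outside
# dot radially along the ray from the inside-dot centroid: pulling it
# toward the cluster carves the middle of the posterior (raising EE),
# pushing it away releases the constraint (lowering EE). The sweep is
# scanned coarsely for a bracket around the band, then bisected. EE is a
# near-continuous function of the dot position (grid steps are well below
# the printed band widths), so a bracket almost always converges.
.tune_probe_dot <- function(prop, band, space, n_scan = 18L,
                            max_bisect = 24L) {
  r <- space$circle_radius
  ins <- prop$dots$label == "inside"
  pc <- c(mean(prop$dots$x[ins]), mean(prop$dots$y[ins]))
  ctr <- prop$true_center
  evals <- 0L
  ee_at <- function(dots) {
    est <- tryCatch(stimulus_ee(dots, space), error = function(e) NULL)
    if (is.null(est)) NA_real_ else est$ee
  }
  for (j in which(!ins)) {
    q0 <- c(prop$dots$x[j], prop$dots$y[j])
    dir <- q0 - pc
    nd <- sqrt(sum(dir^2))
    if (nd < 1e-9) next
    dir <- dir / nd
    t_max <- min(
      if (dir[1] > 0) (space$width - pc[1]) / dir[1]
      else if (dir[1] < 0) -pc[1] / dir[1] else Inf,
      if (dir[2] > 0) (space$height - pc[2]) / dir[2]
      else if (dir[2] < 0) -pc[2] / dir[2] else Inf)
    feasible <- function(t) {
      q <- pc + t * dir
      t <= t_max && t >= 1 && sum((q - ctr)^2) > r^2
    }
    with_probe <- function(t) {
      d <- prop$dots
      q <- pc + t * dir
      d$x[j] <- q[1]; d$y[j] <- q[2]
      d
    }
    ts <- seq(1, t_max, length.out = n_scan)
    ts <- ts[vapply(ts, feasible, logical(1))]
    if (length(ts) < 2) next
    fs <- vapply(ts, function(t) ee_at(with_probe(t)), numeric(1))
    evals <- evals + length(ts)
    hit <- which(fs >= band[1] & fs <= band[2])
    if (length(hit)) {
      d <- with_probe(ts[hit[1]])
      return(list(dots = d, ee = fs[hit[1]], evals = evals))
    }
    for (k in seq_len(length(ts) - 1L)) {
      lo_k <- min(fs[k], fs[k + 1]); hi_k <- max(fs[k], fs[k + 1])
      if (is.na(lo_k) || is.na(hi_k)) next
      if (lo_k < band[1] && hi_k > band[2]) {
        a <- ts[k]; b <- ts[k + 1]
        fa <- fs[k]
        for (it in seq_len(max_bisect)) {
          m <- (a + b) / 2
          if (!feasible(m)) break
          fm <- ee_at(with_probe(m))
          evals <- evals + 1L
          if (is.na(fm)) break
          if (fm >= band[1] && fm <= band[2])
            return(list(dots = with_probe(m), ee = fm, evals = evals))
          # keep the sub-interval that still straddles the band
          if ((fa < band[1]) == (fm < band[1])) { a <- m; fa <- fm }
          else b <- m
        }
      }
    }
  }
  list(dots = NULL, evals = evals)
}

#' @export
print.cq_stimulus <- function(x, ...) {
  cat(sprintf("<cq_stimulus: EE %.2f px in band [%g, %g], %d attempts>\n",
              x$achieved_ee, x$ee_band[1], x$ee_band[2], x$attempts))
  invisible(x)
}

.schedule_row <- function(trial_id, experiment, block, reserve = NA_real_,
                          cost = NA_real_, reward = NA_real_,
                          effort = NA_real_, uncertainty = NA_character_,
                          ee_lo = NA_real_, ee_hi = NA_real_,
                          is_catch = FALSE) {
  data.frame(trial_id = trial_id, experiment = experiment, block = block,
             reserve = reserve, cost = cost, reward = reward,
             effort = effort, uncertainty = uncertainty,
             ee_lo = ee_lo, ee_hi = ee_hi, is_catch = is_catch)
}

#' Active-sampling schedule (exp1)
#'
#' Two initial-reserve levels (95, 130 credits) crossed with two
#' sampling-cost levels (1, 5 credits/sample), one condition per block,
#' 15 trials each (60 total). Block order is a seed-indexed permutation of
#' the four conditions (between-participant counterbalancing).
#'
#' @param seed Integer seed.
#' @return A 60-row schedule data.frame.
#' @export
exp1_schedule <- function(seed = 1L) {
  set.seed(seed)
  cond <- expand.grid(reserve = cq_design$exp1_reserve,
                      cost = cq_design$exp1_cost)
  ord <- sample.int(4L)
  out <- do.call(rbind, lapply(seq_len(4L), function(b) {
    cc <- cond[ord[b], ]
    .schedule_row(trial_id = 0L, experiment = "exp1", block = b,
                  reserve = cc$reserve, cost = cc$cost)[
                    rep(1, cq_design$exp1_trials_per_condition), ]
  }))
  out$trial_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

.shuffled_factorial <- function(cells, reps, seed) {
  set.seed(seed)
  full <- cells[rep(seq_len(nrow(cells)), each = reps), , drop = FALSE]
  full[sample.int(nrow(full)), , drop = FALSE]
}

#' Reward-by-uncertainty passive-choice schedule (exp2)
#'
#' Four reward levels (40, 65, 90, 115 credits) crossed with five EE bands,
#' five repetitions per cell, shuffled: 100 trials.
#'
#' @param seed Integer seed.
#' @return A 100-row schedule data.frame.
#' @export
exp2_schedule <- function(seed = 1L) {
  bands <- cq_design$exp2_ee_bands
  cells <- expand.grid(reward = cq_design$exp2_rewards,
                       band = seq_len(nrow(bands)))
  full <- .shuffled_factorial(cells, 5L, seed)
  .schedule_row(trial_id = seq_len(nrow(full)), experiment = "exp2",
                block = 1L, reward = full$reward,
                uncertainty = paste0("band", full$band),
                ee_lo = bands[full$band, "lo"], ee_hi = bands[full$band, "hi"])
}

#' Reward-by-effort schedule (exp3)
#'
#' Five reward levels (1, 4, 7, 10, 13 apples) crossed with five effort
#' levels (16, 32, 48, 64, 80 % MVC), five repetitions: 125 trials.
#'
#' @param seed Integer seed.
#' @return A 125-row schedule data.frame.
#' @export
exp3_schedule <- function(seed = 1L) {
  cells <- expand.grid(reward = cq_design$exp3_rewards,
                       effort = cq_design$effort_levels)
  full <- .shuffled_factorial(cells, 5L, seed)
  .schedule_row(trial_id = seq_len(nrow(full)), experiment = "exp3",
                block = 1L, reward = full$reward, effort = full$effort)
}

#' Reward-by-effort-by-uncertainty schedule with catch trials (exp4)
#'
#' Four reward levels x five effort levels x uncertainty present/absent
#' (40 trial types), five repetitions over ten blocks (200 main trials).
#' Present-uncertainty trials carry the 31.8-73.95 px EE band; absent
#' trials show the true location (EE 0). One catch trial per block (ten in
#' total): five with EE below 23 px and five above 91 px, each catch level
#' crossed once with each of the five effort levels; catch rewards are
#' drawn from the main reward levels. Total 210 trials.
#'
#' @param seed Integer seed.
#' @return A 210-row schedule data.frame.
#' @export
exp4_schedule <- function(seed = 1L) {
  d <- cq_design
  cells <- expand.grid(reward = d$exp4_rewards, effort = d$effort_levels,
                       uncertainty = c("present", "absent"),
                       stringsAsFactors = FALSE)
  full <- .shuffled_factorial(cells, 5L, seed)
  main <- .schedule_row(trial_id = 0L, experiment = "exp4",
                        block = rep(1:10, each = 20L),
                        reward = full$reward, effort = full$effort,
                        uncertainty = full$uncertainty,
                        ee_lo = ifelse(full$uncertainty == "present",
                                       d$exp4_present_band["lo"], 0),
                        ee_hi = ifelse(full$uncertainty == "present",
                                       d$exp4_present_band["hi"], 0))
  catch_level <- sample(rep(c("catch_low", "catch_high"), each = 5L))
  # pair efforts so each catch level sees all five effort levels once
  eff_low <- sample(d$effort_levels)
  eff_high <- sample(d$effort_levels)
  i_lo <- 0L; i_hi <- 0L
  catch <- do.call(rbind, lapply(1:10, function(b) {
    lv <- catch_level[b]
    if (lv == "catch_low") {
      i_lo <<- i_lo + 1L
      band <- d$exp4_catch_low; eff <- eff_low[i_lo]
    } else {
      i_hi <<- i_hi + 1L
      band <- d$exp4_catch_high; eff <- eff_high[i_hi]
    }
    .schedule_row(trial_id = 0L, experiment = "exp4", block = b,
                  reward = sample(d$exp4_rewards, 1L), effort = eff,
                  uncertainty = lv, ee_lo = band[["lo"]],
                  ee_hi = band[["hi"]], is_catch = TRUE)
  }))
  out <- do.call(rbind, lapply(1:10, function(b) {
    blk <- rbind(main[main$block == b, ], catch[b, ])
    n <- nrow(blk) - 1L
    pos <- sample.int(n + 1L, 1L)  # catch position within the block
    blk[append(seq_len(n), n + 1L, after = pos - 1L), ]
  }))
  out$trial_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
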