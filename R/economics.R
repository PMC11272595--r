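# Trial economy: score, expected-value dynamics, optimal sample count, and
# the exponential information-extraction-rate fit.

#' Define a trial economy
#'
#' @param R0 Initial reward reserve in credits (study levels: 95 low,
#'   130 high).
#' @param eta_s Sampling cost in credits per sample (study levels: 1 low,
#'   5 high).
#' @param eta_e Error cost in credits per pixel (fixed at 1.2 in the task).
#' @return A `cq_econ`.
#' @export
trial_economics <- function(R0, eta_s, eta_e = 1.2) {
  if (R0 <= 0) stop("R0 must be positive")
  if (eta_s < 0) stop("eta_s must be nonnegative")
  if (eta_e <= 0) stop("eta_e must be positive")
  structure(list(R0 = R0, eta_s = eta_s, eta_e = eta_e), class = "cq_econ")
}

#' Trial score
#'
#' Score = R0 - s * eta_s - e * eta_e: the initial reserve minus the
#' sampling spend and the localization-error penalty. Negative scores are
#' allowed unless a floor is supplied.
#'
#' @param econ A `cq_econ`.
#' @param s Number of samples acquired (>= 0).
#' @param e Localization error in pixels (>= 0).
#' @param floor Optional lower bound on the returned score (e.g. 0).
#' @return Score in credits.
#' @export
trial_score <- function(econ, s, e, floor = NULL) {
  stopifnot(inherits(econ, "cq_econ"), all(s >= 0), all(e >= 0))
  sc <- econ$R0 - s * econ$eta_s - e * econ$eta_e
  if (!is.null(floor)) sc <- pmax(sc, floor)
  sc
}

#' Expected-value curve over sample counts
#'
#' EV(s) = R0 - s * eta_s - EE(s) * eta_e, where `ee_curve[i]` is the
#' expected error after `i - 1` acquired samples (the first element is the
#' state given only the initially displayed dot).
#'
#' @param econ A `cq_econ`.
#' @param ee_curve Nonnegative numeric vector of EE values per sample count.
#' @return Numeric vector of EV values, same length as `ee_curve`.
#' @export
expected_value_curve <- function(econ, ee_curve) {
  stopifnot(inherits(econ, "cq_econ"), length(ee_curve) > 0,
            all(ee_curve >= 0))
  s <- seq_along(ee_curve) - 1L
  econ$R0 - s * econ$eta_s - ee_curve * econ$eta_e
}

#' Optimal number of samples
#'
#' The sample count s* maximizing the expected-value curve; ties break to
#' the smallest s (fewer samples weakly dominates at equal EV).
#'
#' @param ev_curve Numeric EV vector; element `i` is EV at `i - 1` samples.
#' @return A list with `s_star` (count), and `ev_curve` as supplied.
#' @export
optimal_samples <- function(ev_curve) {
  stopifnot(length(ev_curve) > 0)
  list(s_star = which.max(ev_curve) - 1L, ev_curve = ev_curve)
}

#' Deviation from optimal sampling
#'
#' @param samples_taken,s_star Nonnegative counts.
#' @return `samples_taken - s_star`; positive values indicate oversampling.
#' @export
deviation_from_optimal <- function(samples_taken, s_star) {
  stopifnot(all(samples_taken >= 0), all(s_star >= 0))
  samples_taken - s_star
}

# Predicted EE decay: (start - ee_inf) * (1 - alpha)^(s - 1) + ee_inf,
# s = 1..length. Linear in ee_inf given alpha, so ee_inf is profiled in
# closed form and the fit reduces to a 1-D bounded search over alpha.
.ee_decay <- function(start, alpha, ee_inf, n_s) {
  g <- (1 - alpha)^(seq_len(n_s) - 1)
  (start - ee_inf) * g + ee_inf
}

.fit_one_alpha <- function(obs, start, eps = 1e-9) {
  n_s <- length(obs)
  sse_at <- function(alpha) {
    g <- (1 - alpha)^(seq_len(n_s) - 1)
    # obs ~ start*g + ee_inf*(1-g); least-squares ee_inf given alpha
    h <- 1 - g
    denom <- sum(h^2)
    ee_inf <- if (denom < eps) mean(obs) else sum(h * (obs - start * g)) / denom
    ee_inf <- max(ee_inf, eps)
    pred <- start * g + ee_inf * h
    c(sse = sum((obs - pred)^2), ee_inf = ee_inf)
  }
  grid <- seq(0.01, 0.99, by = 0.02)
  sse_grid <- vapply(grid, function(a) sse_at(a)[["sse"]], numeric(1))
  a0 <- grid[which.min(sse_grid)]
  opt <- stats::optimize(function(a) sse_at(a)[["sse"]],
                         lower = max(eps, a0 - 0.02),
                         upper = min(1 - eps, a0 + 0.02), tol = 1e-10)
  best <- sse_at(opt$minimum)
  list(alpha = opt$minimum, ee_inf = best[["ee_inf"]],
       sse = best[["sse"]] / n_s)
}

#' Fit the information-extraction rate per trial
#'
#' Models each trial's EE trajectory as an exponential decay towards an
#' asymptote: EE(s) = (EE1 - EEinf) * (1 - alpha)^(s - 1) + EEinf, with the
#' starting level EE1 shared across trials (the across-trial mean EE at the
#' first sample state) and per-trial `alpha` in (0, 1) and `EEinf > 0`
#' minimizing mean squared error. `alpha` is the per-sample fraction of
#' reducible uncertainty removed — the efficiency of the search.
#'
#' @param trajectories A list of `cq_trajectory` objects (see
#'   [active_sampling_episode()]) or a list of numeric EE vectors.
#' @param n_trials_for_start Number of leading trials averaged for the
#'   shared starting level (default: all trials; the four-condition active
#'   task uses its full 60).
#' @return A data.frame with one row per trial: `trial_id`, `alpha`,
#'   `ee_inf`, `sse` (mean squared error), `converged`, and `flagged`
#'   (degenerate or boundary fits). Trials with fewer than 2 EE values are
#'   dropped with a warning.
#' @export
fit_extraction_rate <- function(trajectories, n_trials_for_start = NULL) {
  curves <- lapply(trajectories, function(tr) {
    if (inherits(tr, "cq_trajectory")) tr$ee_per_sample else as.numeric(tr)
  })
  ids <- names(curves)
  if (is.null(ids)) ids <- as.character(seq_along(curves))
  ok <- vapply(curves, length, integer(1)) >= 2L
  if (any(!ok)) {
    warning(sum(!ok), " trajectory(ies) with a single EE value skipped")
    curves <- curves[ok]; ids <- ids[ok]
  }
  if (length(curves) == 0L) stop("no trajectory with >= 2 EE values")
  k <- if (is.null(n_trials_for_start)) length(curves)
       else min(n_trials_for_start, length(curves))
  start <- mean(vapply(curves[seq_len(k)], `[`, numeric(1), 1L))
  fits <- lapply(curves, function(obs) .fit_one_alpha(obs, start))
  data.frame(
    trial_id = ids,
    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    ee_inf = vapply(fits, `[[`, numeric(1), "ee_inf"),
    sse = vapply(fits, `[[`, numeric(1), "sse"),
    converged = TRUE,
    flagged = vapply(seq_along(fits), function(i) {
      fits[[i]]$alpha < 0.02 || fits[[i]]$alpha > 0.98 ||
        stats::var(curves[[i]]) < 1e-10
    }, logical(1)),
    row.names = NULL)
}

#' Inter-sampling intervals of a trajectory
#'
#' @param trajectory A `cq_trajectory`, or a numeric vector of sample
#'   timestamps (seconds from trial onset, strictly increasing).
#' @return A list with `gaps` (successive differences, empty if < 2
#'   samples), `mean` and `median` (NA when undefined).
#' @export
inter_sampling_intervals <- function(trajectory) {
  ts <- if (inherits(trajectory, "cq_trajectory"))
    trajectory$samples$timestamp else as.numeric(trajectory)
  if (length(ts) >= 2 && any(diff(ts) <= 0))
    stop("timestamps must be strictly increasing")
  gaps <- if (length(ts) >= 2) diff(ts) else numeric(0)
  list(gaps = gaps,
       mean = if (length(gaps)) mean(gaps) else NA_real_,
       median = if (length(gaps)) stats::median(gaps) else NA_real_)
}
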