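# Shared fixtures: small search spaces and hand-built posteriors.

small_space <- function(width = 100, height = 100, r = 10, step = 1) {
  search_space(width = width, height = height, circle_radius = r,
               grid_step = step)
}

# A posterior with explicitly chosen candidates and weights (bypasses the
# grid so textbook cases can be asserted exactly).
manual_posterior <- function(cx, cy, w = NULL, space = small_space()) {
  w <- if (is.null(w)) rep(1 / length(cx), length(cx)) else w / sum(w)
  structure(list(space = space, cx = cx, cy = cy, w = w,
                 observations = data.frame(x = numeric(0), y = numeric(0),
                                           label = character(0),
                                           timestamp = numeric(0))),
            class = "cq_posterior")
}

# Independent brute-force EE oracle: plain double loop over candidates.
ee_oracle <- function(cx, cy, w, px, py) {
  px <- unname(px); py <- unname(py)
  total <- 0
  for (i in seq_along(cx)) {
    total <- total + w[i] * sqrt((cx[i] - px)^2 + (cy[i] - py)^2)
  }
  total
}

# Noisy exponential EE trajectory for extraction-rate recovery tests.
make_decay_curve <- function(alpha, ee_start = 90, ee_inf = 15,
                             n_s = 12, sigma = 0) {
  s <- seq_len(n_s)
  (ee_start - ee_inf) * (1 - alpha)^(s - 1) + ee_inf +
    stats::rnorm(n_s, 0, sigma)
}
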