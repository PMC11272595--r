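# Ideal-observer geometry: posterior over candidate circle centres from
# binary inside/outside samples, expected error (EE), and placement.

#' Define a search space for the hidden-circle task
#'
#' The hidden circle has a fixed radius and is centred somewhere on a
#' rectangular touch screen. Candidate centres are discretized on a square
#' grid and restricted so the full circle fits on screen (inset by one
#' radius). The default dimensions (1280 x 715 px) give a screen area of
#' 915,200 px^2, so the 130-px circle covers 5.80% of the search space.
#'
#' @param width,height Screen dimensions in pixels.
#' @param circle_radius Radius of the hidden circle in pixels.
#' @param grid_step Candidate-centre grid spacing in pixels (>= 1). Finer
#'   grids give more precise EE at quadratic cost.
#' @return An object of class `cq_space`.
#' @export
search_space <- function(width = 1280, height = 715, circle_radius = 130,
                         grid_step = 4) {
  stopifnot(is.numeric(width), is.numeric(height), is.numeric(circle_radius),
            is.numeric(grid_step))
  if (width <= 0 || height <= 0) stop("search space dimensions must be positive")
  if (circle_radius <= 0 || circle_radius >= min(width, height) / 2)
    stop("circle_radius must satisfy 0 < r < min(width, height)/2 ",
         "(the circle must fit inside the space)")
  if (grid_step < 1) stop("grid_step must be >= 1")
  structure(list(width = width, height = height,
                 circle_radius = circle_radius, grid_step = grid_step),
            class = "cq_space")
}

#' @export
print.cq_space <- function(x, ...) {
  cat(sprintf("<cq_space %g x %g px, circle radius %g px, grid step %g px>\n",
              x$width, x$height, x$circle_radius, x$grid_step))
  invisible(x)
}

# admissible candidate-centre grid, cached per space geometry
.cq_grid_cache <- new.env(parent = emptyenv())

.candidate_grid <- function(space) {
  key <- paste(space$width, space$height, space$circle_radius,
               space$grid_step, sep = "|")
  hit <- .cq_grid_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- space$circle_radius
  xs <- seq(r, space$width - r, by = space$grid_step)
  ys <- seq(r, space$height - r, by = space$grid_step)
  if (length(xs) == 0L || length(ys) == 0L)
    stop("grid_step too large for this space: no admissible candidate centres")
  g <- list(cx = rep(xs, times = length(ys)), cy = rep(ys, each = length(xs)))
  .cq_grid_cache[[key]] <- g
  g
}

#' Uniform prior over admissible circle centres
#'
#' Candidate centres are grid points at `grid_step` spacing, inset by the
#' circle radius so the hidden circle lies fully on screen; the prior is
#' uniform over these (maximum-entropy default).
#'
#' @param space A `cq_space`.
#' @return A `cq_posterior`: candidate coordinates `cx`, `cy`, weights `w`
#'   (summing to 1), the space, and the observation log.
#' @export
init_posterior <- function(space) {
  stopifnot(inherits(space, "cq_space"))
  g <- .candidate_grid(space)
  structure(list(space = space, cx = g$cx, cy = g$cy,
                 w = rep(1 / length(g$cx), length(g$cx)),
                 observations = data.frame(x = numeric(0), y = numeric(0),
                                           label = character(0),
                                           timestamp = numeric(0))),
            class = "cq_posterior")
}

#' @export
print.cq_posterior <- function(x, ...) {
  cat(sprintf("<cq_posterior: %d candidates in support, %d observations>\n",
              length(x$cx), nrow(x$observations)))
  invisible(x)
}

#' Condition the posterior on one inside/outside sample
#'
#' An `inside` sample retains exactly the candidates within `circle_radius`
#' of the touch (inclusive boundary); an `outside` sample retains the
#' complement. Weights are renormalized; support is always nested within the
#' input support.
#'
#' @param belief A `cq_posterior`.
#' @param x,y Sample coordinates (pixels, within the space).
#' @param label `"inside"` or `"outside"`.
#' @param timestamp Seconds from trial onset (recorded in the log).
#' @return The updated `cq_posterior`.
#' @export
update_posterior <- function(belief, x, y, label = c("inside", "outside"),
                             timestamp = NA_real_) {
  stopifnot(inherits(belief, "cq_posterior"))
  label <- match.arg(label)
  sp <- belief$space
  if (x < 0 || x > sp$width || y < 0 || y > sp$height)
    stop("sample (", x, ", ", y, ") lies outside the search space")
  d2 <- (belief$cx - x)^2 + (belief$cy - y)^2
  r2 <- sp$circle_radius^2
  keep <- if (label == "inside") d2 <= r2 else d2 > r2
  if (!any(keep))
    stop("observation at (", x, ", ", y, ") labelled '", label,
         "' is inconsistent with every remaining candidate centre ",
         "(empty posterior: corrupted log or wrong radius?)")
  belief$cx <- belief$cx[keep]
  belief$cy <- belief$cy[keep]
  w <- belief$w[keep]
  belief$w <- w / sum(w)
  belief$observations <- rbind(
    belief$observations,
    data.frame(x = x, y = y, label = label, timestamp = timestamp))
  belief
}

#' Expected localization error of a placement
#'
#' The probability-weighted mean Euclidean distance between a placement and
#' the candidate circle centres under the current posterior.
#'
#' @param belief A `cq_posterior` with nonempty support.
#' @param placement Numeric length-2 vector `(x, y)`.
#' @return Expected error in pixels.
#' @export
expected_error <- function(belief, placement) {
  stopifnot(inherits(belief, "cq_posterior"), length(placement) == 2)
  if (length(belief$cx) == 0L) stop("empty posterior support")
  sum(belief$w * sqrt((belief$cx - placement[1])^2 +
                      (belief$cy - placement[2])^2))
}

#' Optimal placement: the posterior centroid
#'
#' @param belief A `cq_posterior` with nonempty support.
#' @return Numeric `(x, y)` — the probability-weighted centroid of the
#'   candidate centres, the placement used for the EE uncertainty measure.
#' @export
best_placement <- function(belief) {
  stopifnot(inherits(belief, "cq_posterior"))
  if (length(belief$cx) == 0L) stop("empty posterior support")
  c(x = sum(belief$w * belief$cx), y = sum(belief$w * belief$cy))
}

#' Expected error at the optimal placement
#'
#' The task's operational uncertainty measure: EE evaluated at the posterior
#' centroid (the best possible placement of the localization disk).
#'
#' @param belief A `cq_posterior` with nonempty support.
#' @return A `cq_uncertainty`: `ee` (pixels), `centroid` `(x, y)`, and
#'   `support_size` (candidates with nonzero weight).
#' @export
ee <- function(belief) {
  ctr <- best_placement(belief)
  structure(list(ee = expected_error(belief, ctr),
                 centroid = ctr,
                 support_size = sum(belief$w > 0)),
            class = "cq_uncertainty")
}

#' @export
print.cq_uncertainty <- function(x, ...) {
  cat(sprintf("<EE %.2f px at centroid (%.1f, %.1f), support %d>\n",
              x$ee, x$centroid[1], x$centroid[2], x$support_size))
  invisible(x)
}

#' Generate the inside/outside label for a touch
#'
#' Labels a sample `inside` iff its distance to the true centre is at most
#' the circle radius — the same inclusive boundary used by
#' [update_posterior()], so simulated observations never empty the posterior.
#'
#' @param true_center Numeric `(x, y)` of the hidden circle centre.
#' @param sample Numeric `(x, y)` of the touch.
#' @param space A `cq_space`.
#' @param timestamp Seconds from trial onset.
#' @return A one-row data.frame with columns `x`, `y`, `label`, `timestamp`.
#' @export
simulate_observation <- function(true_center, sample, space,
                                 timestamp = NA_real_) {
  stopifnot(inherits(space, "cq_space"),
            length(true_center) == 2, length(sample) == 2)
  d <- sqrt(sum((true_center - sample)^2))
  data.frame(x = sample[1], y = sample[2],
             label = if (d <= space$circle_radius) "inside" else "outside",
             timestamp = timestamp)
}

#' Euclidean localization error
#'
#' @param placement,true_center Numeric `(x, y)` points.
#' @return Distance in pixels.
#' @export
localization_error <- function(placement, true_center) {
  sqrt(sum((placement - true_center)^2))
}
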