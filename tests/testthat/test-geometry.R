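# Posterior maintenance, expected error, and placement.

test_that("search space validates its geometry", {
  expect_s3_class(search_space(), "cq_space")
  expect_error(search_space(200, 200, circle_radius = 130), "fit")
  expect_error(search_space(-5, 100), "positive")
  expect_error(search_space(grid_step = 0.5), "grid_step")
})

test_that("the prior is uniform over the inset candidate grid", {
  b <- init_posterior(small_space(100, 100, r = 10, step = 10))
  expect_true(all(b$cx >= 10 & b$cx <= 90))
  expect_true(all(abs(b$w - b$w[1]) < 1e-15))
  expect_equal(sum(b$w), 1, tolerance = 1e-12)
  expect_equal(nrow(b$observations), 0L)

  # near-degenerate: containment still leaves at least the centre point
  tight <- init_posterior(small_space(40, 40, r = 19, step = 1))
  expect_gte(length(tight$cx), 1L)
})

test_that("inside/outside updates filter candidates by the distance rule", {
  b <- manual_posterior(c(0, 30), c(0, 0))
  inside <- update_posterior(b, 0, 0, "inside")
  expect_equal(cbind(inside$cx, inside$cy), cbind(0, 0))
  expect_equal(inside$w, 1)

  outside <- update_posterior(b, 0, 0, "outside")
  expect_equal(cbind(outside$cx, outside$cy), cbind(30, 0))

  # a labelling consistent with no candidate is an explicit error
  expect_error(update_posterior(inside, 0, 0, "outside"), "inconsistent")
  expect_error(update_posterior(b, 500, 0, "inside"), "outside the search")
})

test_that("retained fraction after an inside sample matches brute-force counting", {
  sp <- small_space(50, 50, r = 10, step = 1)
  b <- init_posterior(sp)
  b2 <- update_posterior(b, 25, 25, "inside")
  n_manual <- 0L
  for (x in seq(10, 40)) {
    for (y in seq(10, 40)) {
      if ((x - 25)^2 + (y - 25)^2 <= 100) n_manual <- n_manual + 1L
    }
  }
  expect_identical(length(b2$cx), n_manual)
})

test_that("expected error matches hand cases and the loop oracle", {
  single <- manual_posterior(100, 100)
  expect_equal(expected_error(single, c(100, 100)), 0)

  pair <- manual_posterior(c(0, 0), c(0, 10))
  expect_equal(expected_error(pair, c(0, 5)), 5)

  set.seed(41)
  cx <- runif(20, 0, 100); cy <- runif(20, 0, 100)
  w <- runif(20); w <- w / sum(w)
  bel <- manual_posterior(cx, cy, w)
  p <- c(runif(1, 0, 100), runif(1, 0, 100))
  expect_equal(expected_error(bel, p), ee_oracle(cx, cy, w, p[1], p[2]),
               tolerance = 1e-12)
})

test_that("best placement is the probability-weighted centroid", {
  expect_equal(unname(best_placement(manual_posterior(7, 3))), c(7, 3))
  expect_equal(unname(best_placement(manual_posterior(c(0, 10), c(0, 0)))),
               c(5, 0))
  expect_equal(unname(best_placement(
    manual_posterior(c(0, 8), c(0, 0), w = c(0.75, 0.25)))), c(2, 0))
})

test_that("ee() is the oracle EE evaluated at the centroid", {
  expect_equal(ee(manual_posterior(50, 50))$ee, 0)

  pair <- ee(manual_posterior(c(0, 0), c(0, 10)))
  expect_equal(unname(pair$centroid), c(0, 5))
  expect_equal(pair$ee, 5)

  set.seed(42)
  cx <- runif(30, 0, 100); cy <- runif(30, 0, 100)
  w <- runif(30); w <- w / sum(w)
  bel <- manual_posterior(cx, cy, w)
  est <- ee(bel)
  expect_equal(est$ee,
               ee_oracle(cx, cy, w, est$centroid[1], est$centroid[2]),
               tolerance = 1e-12)
  # centroid inside the support's bounding box (convex-hull necessary cond.)
  expect_true(est$centroid[1] >= min(cx) && est$centroid[1] <= max(cx))
  expect_true(est$centroid[2] >= min(cy) && est$centroid[2] <= max(cy))
})

test_that("observation labelling uses the same inclusive boundary as updates", {
  sp <- small_space()
  expect_identical(simulate_observation(c(50, 50), c(50, 60), sp)$label,
                   "inside")   # dist == r exactly
  expect_identical(simulate_observation(c(50, 50), c(50, 60.0001), sp)$label,
                   "outside")
})

test_that("localization error is Euclidean distance", {
  expect_equal(localization_error(c(1, 2), c(1, 2)), 0)
  expect_equal(localization_error(c(0, 0), c(3, 4)), 5)
})

test_that("support is nested and the true centre survives simulated sampling", {
  sp <- small_space(80, 80, r = 15, step = 1)
  set.seed(7)
  for (rep in 1:5) {
    b <- init_posterior(sp)
    truth_i <- sample(length(b$cx), 1)
    truth <- c(b$cx[truth_i], b$cy[truth_i])
    for (k in 1:8) {
      pt <- c(runif(1, 0, 80), runif(1, 0, 80))
      obs <- simulate_observation(truth, pt, sp)
      before <- paste(b$cx, b$cy)
      b <- update_posterior(b, obs$x, obs$y, obs$label)
      expect_true(all(paste(b$cx, b$cy) %in% before))  # nested support
      expect_true(paste(truth[1], truth[2]) %in% paste(b$cx, b$cy))
    }
  }
})

test_that("EE at grid_step 4 is within the discretization bound of step 1", {
  set.seed(9)
  obs_sets <- replicate(3, {
    truth <- c(runif(1, 20, 80), runif(1, 20, 80))
    pts <- cbind(runif(5, 0, 100), runif(5, 0, 100))
    list(truth = truth, pts = pts)
  }, simplify = FALSE)
  for (os in obs_sets) {
    ees <- sapply(c(1, 4), function(st) {
      sp <- small_space(100, 100, r = 15, step = st)
      b <- init_posterior(sp)
      for (i in 1:5) {
        o <- simulate_observation(os$truth, os$pts[i, ], sp)
        b <- update_posterior(b, o$x, o$y, o$label)
      }
      ee(b)$ee
    })
    expect_lt(abs(ees[1] - ees[2]), 8)  # grid_step * 2
  }
})
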