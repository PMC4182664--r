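# Geometry substrate: rotations, chord law, angles, circle fits,
# point-line distance, rigid transforms.

test_that("rotate_about performs exact planar rotations", {
  expect_equal(rotate_about(c(1, 0), c(0, 0), 90), c(0, 1),
               tolerance = 1e-12)
  p <- c(3.2, -7.5)
  expect_equal(rotate_about(p, p, 123.4), p)   # center is a fixed point
  # chord length of a -15 degree turn at radius 100:
  # 2 * 100 * sin(7.5 deg) = 26.105238444010315
  moved <- rotate_about(c(100, 0), c(0, 0), -15)
  expect_equal(sqrt(sum((moved - c(100, 0))^2)), 26.105238444010315,
               tolerance = 1e-12)
  expect_error(rotate_about(c(1, 0), c(0, 0), NaN), "finite")
})

test_that("chord_displacement matches 2 r sin(theta/2)", {
  expect_equal(chord_displacement(123, 0), 0)
  expect_equal(chord_displacement(0, 77), 0)
  expect_equal(chord_displacement(100, 180), 200)
  expect_equal(chord_displacement(100, 15), 26.105238444010315,
               tolerance = 1e-12)
  expect_equal(chord_displacement(50, 360), 0, tolerance = 1e-12)
  expect_error(chord_displacement(-1, 10), "non-negative")
})

test_that("angle_at_vertex is unsigned, bounded and stable near 180", {
  expect_equal(angle_at_vertex(c(0, 0), c(1, 0), c(0, -1)), 90)
  expect_equal(angle_at_vertex(c(0, 0), c(1, 0), c(2, 0)), 0)
  near <- angle_at_vertex(c(0, 0), c(1, 0), c(-1, 1e-9))
  expect_gt(near, 180 - 1e-6)
  expect_lte(near, 180)
  expect_error(angle_at_vertex(c(0, 0), c(0, 0), c(1, 1)), "degenerate")
})

test_that("perpendicular_distance agrees with the cross-product form", {
  expect_equal(perpendicular_distance(c(0, 1), c(0, 0), c(1, 0)), 1)
  expect_equal(perpendicular_distance(c(5, 5), c(0, 0), c(1, 1)), 0)
  expect_equal(perpendicular_distance(c(3, 4), c(0, 0), c(1, 1)),
               1 / sqrt(2), tolerance = 1e-12)
  expect_error(perpendicular_distance(c(1, 1), c(0, 0), c(0, 0)),
               "nonzero")
})

test_that("fit_circle returns the circumcircle for three points", {
  f <- fit_circle(rbind(c(1, 0), c(0, 1), c(-1, 0)))
  expect_equal(f$center, c(0, 0), tolerance = 1e-12)
  expect_equal(f$radius, 1, tolerance = 1e-12)
  expect_equal(f$residuals, rep(0, 3), tolerance = 1e-12)
  expect_error(fit_circle(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
  expect_error(fit_circle(rbind(c(0, 0), c(1, 1))), "at least 3")
})

test_that("fit_circle recovers the generator's canine circle exactly", {
  p <- skull_params()
  arc <- canine_arc_points(p, n = 5)
  f <- fit_circle(arc)
  cfg <- generate_skull(p)
  expect_equal(f$center, unname(cfg$landmarks["VIRTUAL_POINT", ]),
               tolerance = 1e-9)
  expect_equal(f$radius, p$canine_radius, tolerance = 1e-9)
})

test_that("fit_circle least squares is accurate under small noise", {
  set.seed(42)
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  pts <- cbind(cos(th), sin(th)) + matrix(rnorm(40, sd = 0.01), ncol = 2)
  f <- fit_circle(pts)
  expect_lt(sqrt(sum(f$center^2)), 0.01)
  # independent oracle: two-stage grid refinement of the geometric
  # least-squares objective (variance of radii about a candidate center)
  obj <- function(c_) {
    r <- sqrt((pts[, 1] - c_[1])^2 + (pts[, 2] - c_[2])^2)
    sum((r - mean(r))^2)
  }
  best <- c(0, 0); span <- 0.05
  for (pass in 1:3) {
    grid <- expand.grid(x = seq(best[1] - span, best[1] + span,
                                length.out = 21),
                        y = seq(best[2] - span, best[2] + span,
                                length.out = 21))
    vals <- apply(grid, 1, obj)
    best <- as.numeric(grid[which.min(vals), ])
    span <- span / 8
  }
  expect_lt(sqrt(sum((f$center - best)^2)), 5e-3)
})

test_that("rigid transforms are isometries and compose associatively", {
  set.seed(7)
  for (i in 1:200) {
    t1 <- rigid_transform(runif(1, -180, 180), runif(2, -50, 50),
                          runif(2, -20, 20))
    t2 <- rigid_transform(runif(1, -180, 180), runif(2, -50, 50),
                          runif(2, -20, 20))
    p <- runif(2, -100, 100); q <- runif(2, -100, 100)
    d0 <- sqrt(sum((p - q)^2))
    d1 <- sqrt(sum((apply_transform(t1, p) - apply_transform(t1, q))^2))
    expect_equal(d1, d0, tolerance = 1e-9)
    expect_equal(apply_transform(compose_transforms(t2, t1), p),
                 apply_transform(t2, apply_transform(t1, p)),
                 tolerance = 1e-9)
    expect_equal(apply_transform(
      compose_transforms(invert_transform(t1), t1), p), p,
      tolerance = 1e-9)
  }
})

test_that("chord law links rotate_about and chord_displacement", {
  set.seed(11)
  for (i in 1:200) {
    p <- runif(2, -100, 100); ctr <- runif(2, -100, 100)
    th <- runif(1, -360, 360)
    d <- sqrt(sum((rotate_about(p, ctr, th) - p)^2))
    expect_equal(d, chord_displacement(sqrt(sum((p - ctr)^2)), th),
                 tolerance = 1e-9)
  }
})
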