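test_that("compute_plax recovers the major axis of voxelized spheroids", {
  # axis-aligned prolate spheroid: symmetry forces the major axis onto x
  g <- ellipsoid_mask(semi = c(45, 20, 20))
  ax <- compute_plax(g)
  expect_gte(abs(sum(ax$direction * c(1, 0, 0))), 0.9999)
  expect_equal(ax$anchor, c(0, 0, 0), tolerance = 1e-6)
  expect_lt(ax$t_min, 0); expect_gt(ax$t_max, 0)

  # rotated 30 degrees about z before voxelization
  R <- rot_z(30)
  gr <- ellipsoid_mask(semi = c(45, 20, 20), rotation = R)
  axr <- compute_plax(gr)
  expect_lt(angle_between_lines(axr$direction, R %*% c(1, 0, 0)), 1)
})

test_that("compute_plax rejects degenerate inputs", {
  ball <- ellipsoid_mask(semi = c(20, 20, 20))
  expect_error(compute_plax(ball), "ambiguous")
  empty <- volume_grid(array(0L, c(4, 4, 4)))
  expect_error(compute_plax(empty), "empty")
})

test_that("compute_plax is equivariant under rigid motion of the affine", {
  g <- ellipsoid_mask(semi = c(45, 20, 20))
  ax <- compute_plax(g)
  R <- rot_y(25) %*% rot_z(40)
  Tr <- rbind(cbind(R, c(10, -4, 7)), c(0, 0, 0, 1))
  g2 <- g; g2$affine <- Tr %*% g$affine
  ax2 <- compute_plax(g2)
  expect_lt(angle_between_lines(ax2$direction, R %*% ax$direction), 1e-6)
  expect_equal(as.numeric(ax2$anchor),
               as.numeric((Tr %*% c(ax$anchor, 1))[1:3]), tolerance = 1e-6)
})

test_that("orient_base_to_apex points the axis at the narrow end", {
  ph <- default_phantom()
  ax <- orient_base_to_apex(compute_plax(ph$lv_mask), ph$lv_mask)
  expect_gt(sum(ax$direction * ph$true_axis$direction), 0.999)
  # idempotence on an already-oriented axis
  ax2 <- orient_base_to_apex(ax, ph$lv_mask)
  expect_equal(ax2$direction, ax$direction)
  expect_equal(c(ax2$t_min, ax2$t_max), c(ax$t_min, ax$t_max))
})

test_that("orient_base_to_apex errors on symmetric shapes unless forced", {
  # closed cylinder: both terminal cross-sections identical
  n <- c(41, 41, 61)
  g <- volume_grid(array(0L, n), spacing = c(1, 1, 1),
                   origin = -(n - 1) / 2)
  P <- voxel_centers(g)
  inside <- P[, 1]^2 + P[, 2]^2 <= 15^2 & abs(P[, 3]) <= 25
  g$data <- array(as.integer(inside), n)
  ax <- compute_plax(g)
  expect_error(orient_base_to_apex(ax, g), "ambiguous")
  kept <- orient_base_to_apex(ax, g, force = "keep")
  expect_equal(kept$direction, ax$direction)
  flipped <- orient_base_to_apex(ax, g, force = "flip")
  expect_equal(flipped$direction, -ax$direction)
})

test_that("angle_between_lines folds to [0, 90] and ignores orientation", {
  expect_equal(angle_between_lines(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_between_lines(c(0, 0, 1), c(0, 0, -1)), 0)
  expect_equal(angle_between_lines(c(1, 0, 0), c(1, 1, 0) / sqrt(2)), 45)
  expect_error(angle_between_lines(c(0, 0, 0), c(1, 0, 0)), "zero")
  set.seed(7)
  for (i in 1:20) {
    d1 <- rnorm(3); d2 <- rnorm(3)
    a <- angle_between_lines(d1, d2)
    expect_equal(a, angle_between_lines(d2, d1))
    expect_equal(a, angle_between_lines(-d1, d2))
    expect_true(a >= 0 && a <= 90)
  }
})

test_that("line_mean_distance matches closed-form cases and the sampling oracle", {
  segA <- lv_axis(c(0, 0, 0), c(1, 0, 0), -40, 40)
  expect_equal(line_mean_distance(segA, segA), 0)
  segB <- lv_axis(c(0, 2, 0), c(1, 0, 0), -40, 40)
  expect_equal(line_mean_distance(segA, segB), 2)
  expect_equal(line_mean_distance(segB, segA), 2)  # symmetric

  # segB = segA rotated 10 deg about the common midpoint: distance of the
  # sample at parameter t to the other infinite line is |t| sin(10 deg)
  th <- 10 * pi / 180
  segC <- lv_axis(c(0, 0, 0), c(cos(th), sin(th), 0), -40, 40)
  oracle <- mean(abs(seq(-40, 40, by = 1))) * sin(th)
  expect_equal(line_mean_distance(segA, segC), oracle, tolerance = 1e-12)
  expect_error(line_mean_distance(segA, segB, step_mm = 0), "step_mm")
})

test_that("azimuth_about_axis respects the right-hand convention", {
  ax <- lv_axis(c(0, 0, 0), c(0, 0, 1), 0, 10)
  expect_equal(azimuth_about_axis(c(5, 0, 3), ax, c(1, 0, 0)), 0)
  expect_equal(azimuth_about_axis(c(0, 5, -2), ax, c(1, 0, 0)), 90)
  expect_error(azimuth_about_axis(c(0, 0, 5), ax, c(1, 0, 0)), "axis")
  expect_error(azimuth_about_axis(c(1, 1, 0), ax, c(0, 0, 1)), "orthogonal")
  # reflection through the (axis, ref_dir) plane flips the sign mod 360
  set.seed(11)
  for (i in 1:20) {
    p <- c(rnorm(2), runif(1, 0, 10))
    if (sqrt(sum(p[1:2]^2)) < 1e-3) next
    a1 <- azimuth_about_axis(p, ax, c(1, 0, 0))
    a2 <- azimuth_about_axis(p * c(1, -1, 1), ax, c(1, 0, 0))
    wrap <- (a1 + a2) %% 360
    expect_lt(min(wrap, 360 - wrap), 1e-9)
  }
})

test_that("compare_axes combines distance and angle", {
  segA <- lv_axis(c(0, 0, 0), c(1, 0, 0), -40, 40)
  same <- compare_axes(segA, segA)
  expect_equal(same$mean_distance_mm, 0)
  expect_equal(same$angle_deg, 0)
  off <- compare_axes(segA, lv_axis(c(0, 1.2, 0), c(1, 0, 0), -40, 40))
  expect_equal(off$mean_distance_mm, 1.2)
  expect_equal(off$angle_deg, 0)
  th <- 6.9 * pi / 180
  rot <- compare_axes(segA, lv_axis(c(0, 0, 0), c(cos(th), sin(th), 0), -40, 40))
  expect_equal(rot$angle_deg, 6.9, tolerance = 1e-9)
  expect_equal(rot$mean_distance_mm, mean(abs(seq(-40, 40, 1))) * sin(th),
               tolerance = 1e-12)
})
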