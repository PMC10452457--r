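test_that("region planes trisect base-to-cavity-tip and honor the fraction rule", {
  ph <- default_phantom()
  res <- default_result()
  pl <- res$planes
  # phantom construction: base slice center 0.75, cavity tip 81.75, apex
  # tip 89.25 mm along the true axis; planes computed in the pipeline's
  # anchor-relative coordinate, so compare spans and absolute positions
  t_anchor <- as.numeric(axial_coord(ph$true_axis, res$axis$anchor))
  sp <- grid_spacing(ph$lv_mask)
  expect_equal(pl$t0 + t_anchor, 0.75, tolerance = 0.51)
  expect_equal(pl$t3 + t_anchor, 81.75, tolerance = 0.5 * sp[3] + 0.01)
  expect_equal(pl$t4 + t_anchor, 89.25, tolerance = 0.5 * sp[3] + 0.01)
  # equal axial spans, exact by construction
  spans <- c(pl$t1 - pl$t0, pl$t2 - pl$t1, pl$t3 - pl$t2)
  expect_lt(max(spans) - min(spans), 1e-6)

  # fraction rule: closed form t3 = t0 + (1 - f) (t4 - t0)
  ms <- default_myoset()
  ax <- orient_base_to_apex(compute_plax(ph$lv_mask), ph$lv_mask)
  plf <- region_planes(ms, ax, apex_rule = 0.2)
  expect_equal(plf$t3, plf$t0 + 0.8 * (plf$t4 - plf$t0), tolerance = 1e-12)
  expect_equal(plf$t1, plf$t0 + (plf$t3 - plf$t0) / 3, tolerance = 1e-12)
  expect_error(region_planes(ms, ax, apex_rule = "nope"), "apex_rule")
})

test_that("sector_label implements the AHA ordering and apical offsets", {
  sch <- sector_scheme(c(1, 0, 0))
  expect_equal(sector_label("apex", 123.4, sch), 17L)
  expect_equal(sector_label("basal", 30, sch), 1L)
  expect_equal(sector_label("mid", 30, sch), 7L)
  expect_equal(sector_label("apical", 30, sch), 13L)
  expect_equal(sector_label("apical", 300, sch), 14L)
  # boundaries are closed-left / open-right
  expect_equal(sector_label("basal", c(0, 60, 120, 180, 240, 300, 359.99), sch),
               c(1L, 6L, 5L, 4L, 3L, 2L, 2L))
  expect_equal(sector_label("mid", c(0, 60), sch), c(7L, 12L))
  expect_equal(sector_label("apical", c(345, 75, 165, 255, 344.99), sch),
               c(13L, 16L, 15L, 14L, 14L))
  # total after wrapping
  expect_equal(sector_label("basal", 360 + 30, sch), 1L)
})

test_that("assigned labels partition the shell", {
  res <- default_result()
  myo <- res$myo$data != 0
  labs <- res$labels$data
  expect_true(all(labs[myo] >= 1 & labs[myo] <= 17))
  expect_true(all(labs[!myo] == 0))
  expect_setequal(unique(as.vector(labs[myo])), 1:17)
})

test_that("rotating the RV point by +60 degrees cycles the basal/mid labels", {
  ph <- default_phantom()
  ms <- default_myoset()
  ax <- orient_base_to_apex(compute_plax(ph$lv_mask), ph$lv_mask)
  # rv at azimuth 0 and rotated +60 about the axis (right-hand rule)
  rot60 <- rot_z(60)
  base <- assign_segments(ms, ax, ph$rv_point)
  turned <- assign_segments(ms, ax, as.numeric(rot60 %*% ph$rv_point))
  # the new anterior territory is the old anterolateral one, etc.
  cyc <- rbind(c(1, 6), c(6, 5), c(5, 4), c(4, 3), c(3, 2), c(2, 1),
               c(7, 12), c(12, 11), c(11, 10), c(10, 9), c(9, 8), c(8, 7))
  for (i in seq_len(nrow(cyc))) {
    expect_identical(turned$labels$data == cyc[i, 1],
                     base$labels$data == cyc[i, 2])
  }
  expect_identical(turned$labels$data == 17, base$labels$data == 17)
})

test_that("assign_segments validates the RV point", {
  ph <- default_phantom()
  ms <- default_myoset()
  ax <- orient_base_to_apex(compute_plax(ph$lv_mask), ph$lv_mask)
  on_axis <- ax$anchor + 10 * ax$direction
  expect_error(assign_segments(ms, ax, on_axis), "on the long axis")
  above <- ph$rv_point + c(0, 0, 200)
  expect_warning(res <- assign_segments(ms, ax, above), "clamped")
  expect_setequal(unique(as.vector(res$labels$data)), 0:17)
})

test_that("close_segments is the identity at radius 0 and fills punched holes", {
  res <- default_result()
  expect_identical(close_segments(res, 0)$labels$data, res$labels$data)

  # toy result: one cubic segment with a punched interior voxel
  n <- c(11, 11, 11)
  labs <- array(0L, n); labs[3:9, 3:9, 3:9] <- 1L
  myo <- labs
  labs[6, 6, 6] <- 0L
  toy <- structure(list(labels = volume_grid(labs, spacing = c(1, 1, 1)),
                        myo = volume_grid(myo, spacing = c(1, 1, 1))),
                   class = "segmentation_result")
  closed <- close_segments(toy, 2)
  expect_equal(closed$labels$data[6, 6, 6], 1L)
  expect_identical(closed$labels$data > 0, myo > 0)
})

test_that("closing preserves the partition on the phantom", {
  res <- default_result()  # run_asset already applied closing (radius 2)
  myo <- res$myo$data != 0
  expect_true(all((res$labels$data > 0) == myo))
  reclosed <- close_segments(res, 2)
  expect_true(all((reclosed$labels$data > 0) == myo))
  expect_setequal(unique(as.vector(reclosed$labels$data[myo])), 1:17)
})

test_that("segment DSC degrades smoothly under axis perturbation", {
  ph <- default_phantom()
  ms <- default_myoset()
  ax <- orient_base_to_apex(compute_plax(ph$lv_mask), ph$lv_mask)
  mean_dsc_at <- function(tilt_deg) {
    R <- rot_x(tilt_deg)
    d <- as.numeric(R %*% ax$direction)
    axp <- lv_axis(ax$anchor, d, ax$t_min, ax$t_max)
    pl <- region_planes(ms, axp)
    res <- suppressWarnings(assign_segments(ms, axp, ph$rv_point, planes = pl))
    evaluate_pair(res$labels, ph$truth_labels)$mean_dsc
  }
  d0 <- mean_dsc_at(0); d3 <- mean_dsc_at(3.5); d7 <- mean_dsc_at(7)
  expect_gt(d0, d3 - 0.005)
  expect_gt(d3, d7 - 0.005)
  expect_gt(d0, d7)
})

test_that("run_asset rejects a missing or on-axis RV point", {
  ph <- default_phantom()
  expect_error(run_asset(ph$lv_mask, ph$true_axis$anchor + c(0, 0, 40)),
               "on the long axis")
})
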