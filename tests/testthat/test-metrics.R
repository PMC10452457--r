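# Brute-force oracles on tiny instances: boundary extraction by explicit
# neighbor checks and all-pairs nearest distances, independent of the
# package's distance-transform path.
brute_boundary <- function(a) {
  d <- dim(a)
  idx <- which(a != 0, arr.ind = TRUE)
  on_b <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    for (ax in 1:3) for (s in c(-1, 1)) {
      j <- i; j[ax] <- j[ax] + s
      if (j[ax] < 1 || j[ax] > d[ax] || a[j[1], j[2], j[3]] == 0) {
        on_b[r] <- TRUE
      }
    }
  }
  idx[on_b, , drop = FALSE]
}

brute_mda <- function(ga, gb) {
  pa <- voxel_to_world(ga, brute_boundary(ga$data) - 1)
  pb <- voxel_to_world(gb, brute_boundary(gb$data) - 1)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  d <- sqrt(pmax(d2, 0))
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

mk <- function(arr, spacing = c(1, 1, 1)) volume_grid(arr, spacing = spacing)

test_that("dice handles identity, disjointness and arithmetic", {
  a <- array(0L, c(8, 8, 8)); a[2:5, 2:5, 2:5] <- 1L
  b <- array(0L, c(8, 8, 8)); b[6:8, 6:8, 6:8] <- 1L
  expect_equal(dice(mk(a), mk(a)), 1)
  expect_equal(dice(mk(a), mk(b)), 0)
  # |A| = |B| = 100, |A ^ B| = 50 -> 0.5
  a2 <- array(0L, c(10, 10, 10)); a2[1:100] <- 1L
  b2 <- array(0L, c(10, 10, 10)); b2[51:150] <- 1L
  expect_equal(dice(mk(a2), mk(b2)), 0.5)
  expect_equal(dice(mk(a2), mk(b2)), dice(mk(b2), mk(a2)))
  expect_warning(e <- dice(mk(array(0L, c(4, 4, 4))), mk(array(0L, c(4, 4, 4)))),
                 "empty")
  expect_equal(e, 1)
  g1 <- mk(a); g2 <- mk(a); g2$affine[1, 4] <- 5
  expect_error(dice(g1, g2), "same grid")
})

test_that("MDA matches slab geometry and the brute-force oracle", {
  a <- array(0L, c(9, 9, 9)); a[, , 3] <- 1L
  b <- array(0L, c(9, 9, 9)); b[, , 6] <- 1L
  expect_equal(mean_distance_to_agreement(mk(a), mk(b)), 3)
  expect_equal(mean_distance_to_agreement(mk(a), mk(a)), 0)
  expect_error(mean_distance_to_agreement(mk(a), mk(array(0L, c(9, 9, 9)))),
               "nonempty")

  # anisotropic slab: physical, not index, distance
  expect_equal(mean_distance_to_agreement(mk(a, c(1, 1, 1.5)), mk(b, c(1, 1, 1.5))),
               4.5)

  # 10^3 cube vs the same cube shifted 2 voxels: exhaustive oracle
  ca <- array(0L, c(14, 14, 14)); ca[2:11, 2:11, 2:11] <- 1L
  cb <- array(0L, c(14, 14, 14)); cb[4:13, 2:11, 2:11] <- 1L
  expect_equal(mean_distance_to_agreement(mk(ca), mk(cb)),
               brute_mda(mk(ca), mk(cb)), tolerance = 1e-12)

  # random blobs, several seeds
  set.seed(42)
  for (i in 1:4) {
    ra <- array(as.integer(runif(6^3) > 0.5), c(6, 6, 6))
    rb <- array(as.integer(runif(6^3) > 0.5), c(6, 6, 6))
    if (!any(ra) || !any(rb)) next
    expect_equal(mean_distance_to_agreement(mk(ra, c(1, 2, 1)), mk(rb, c(1, 2, 1))),
                 brute_mda(mk(ra, c(1, 2, 1)), mk(rb, c(1, 2, 1))),
                 tolerance = 1e-12)
  }
})

test_that("evaluate_pair reports per-label metrics with unweighted averages", {
  res <- default_result()
  truth <- default_phantom()$truth_labels
  m <- evaluate_pair(res$labels, truth)
  expect_equal(nrow(m$per_segment), 17)
  expect_equal(m$per_segment$label, 1:17)
  # self-consistency: rows recomputed with the single-pair operations
  for (l in c(1, 9, 17)) {
    ga <- volume_grid(array(as.integer(res$labels$data == l), dim(res$labels$data)),
                      res$labels$affine)
    gb <- volume_grid(array(as.integer(truth$data == l), dim(truth$data)),
                      truth$affine)
    row <- m$per_segment[m$per_segment$label == l, ]
    expect_equal(row$dsc, dice(ga, gb))
    expect_equal(row$mda_mm, mean_distance_to_agreement(ga, gb))
  }
  expect_equal(m$mean_dsc, mean(m$per_segment$dsc))
  expect_equal(m$sd_dsc, sd(m$per_segment$dsc))

  # identical maps
  m2 <- evaluate_pair(truth, truth)
  expect_true(all(m2$per_segment$dsc == 1))
  expect_true(all(m2$per_segment$mda_mm == 0))
  expect_equal(m2$sd_dsc, 0)

  # one label erased from B
  er <- truth
  er$data[er$data == 5] <- 0L
  m3 <- evaluate_pair(truth, er)
  row5 <- m3$per_segment[m3$per_segment$label == 5, ]
  expect_equal(row5$dsc, 0)
  expect_true(is.na(row5$mda_mm))
  expect_match(row5$note, "missing")
  expect_equal(nrow(m3$per_segment), 17)  # labels present in either map
})

test_that("write_report emits a per-segment CSV with mean/sd footer", {
  truth <- default_phantom()$truth_labels
  m <- evaluate_pair(truth, truth)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(m, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 19)
  expect_equal(tab$name[18:19], c("mean", "sd"))
  expect_equal(tab$dsc[1:17], rep(1, 17))
})
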