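# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; no binary fixtures on disk.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

default_phantom <- function() memo("phantom", make_lv_phantom())

default_result <- function() memo("result", {
  ph <- default_phantom()
  suppressWarnings(run_asset(ph$lv_mask, ph$rv_point))
})

surface_result <- function() memo("surface", {
  ph <- default_phantom()
  suppressWarnings(run_asset(ph$lv_mask, ph$rv_point,
                             asset_config(mode = "surface_closing")))
})

default_myoset <- function() memo("myoset", {
  make_myocardium(default_phantom()$lv_mask)
})

# Voxelized triaxial ellipsoid mask, optionally rotated before voxelization.
ellipsoid_mask <- function(semi = c(45, 20, 20), spacing = c(1, 1, 1),
                           rotation = diag(3), margin = 3) {
  half <- max(semi) + margin
  n <- 2 * ceiling(half / spacing) # per-axis counts (vector)
  origin <- -(n - 1) / 2 * spacing
  g <- volume_grid(array(0L, n), spacing = spacing, origin = origin)
  P <- voxel_centers(g)
  L <- P %*% rotation  # world -> body frame (rows times R == t(R^T p))
  inside <- (L[, 1] / semi[1])^2 + (L[, 2] / semi[2])^2 +
    (L[, 3] / semi[3])^2 <= 1
  g$data <- array(as.integer(inside), dim(g$data))
  g
}

rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}
rot_y <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
}
rot_x <- function(deg) {
  r <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3, 3)
}

# Azimuthal width of one label's voxels, measured from the scheme's nominal
# lower boundary (handles the wrap of the apical sectors).
label_azimuth_width <- function(result, label) {
  sel <- result$labels$data == label
  P <- voxel_centers(result$labels, sel)
  th <- azimuth_about_axis(P, result$axis, result$scheme$ref_dir)
  lo <- aha_segment_table()$theta_lo[label]
  rel <- (th - lo) %% 360
  max(rel) - min(rel)
}
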