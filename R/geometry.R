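#' Oriented 3D axis segment
#'
#' The parasternal long axis (PLAX) is represented as an anchor point, a unit
#' direction (oriented base to apex once [orient_base_to_apex] has run), and
#' the axial extent `[t_min, t_max]` of the mask projected onto the
#' direction, with `t = 0` at the anchor. All quantities in mm.
#'
#' @param anchor length-3 point, mm.
#' @param direction length-3 vector; normalized by the constructor.
#' @param t_min,t_max axial extent in mm relative to `anchor`;
#'   `t_min < t_max`.
#' @return an object of class `lv_axis`.
#' @export
lv_axis <- function(anchor, direction, t_min, t_max) {
  anchor <- as.numeric(anchor); direction <- as.numeric(direction)
  stopifnot(length(anchor) == 3, length(direction) == 3)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("axis direction must be a nonzero vector")
  if (!(t_min < t_max)) stop("axis extent requires t_min < t_max")
  structure(list(anchor = anchor, direction = direction / nrm,
                 t_min = as.numeric(t_min), t_max = as.numeric(t_max)),
            class = "lv_axis")
}

#' @export
print.lv_axis <- function(x, ...) {
  cat(sprintf("<lv_axis> anchor (%.2f, %.2f, %.2f) mm, direction (%.4f, %.4f, %.4f), extent [%.2f, %.2f] mm\n",
              x$anchor[1], x$anchor[2], x$anchor[3],
              x$direction[1], x$direction[2], x$direction[3],
              x$t_min, x$t_max))
  invisible(x)
}

#' Axial coordinate of points relative to an axis
#'
#' @param axis an [lv_axis].
#' @param xyz n x 3 matrix of mm points.
#' @return numeric vector of signed projections `(p - anchor) . direction`.
#' @export
axial_coord <- function(axis, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  sweep(xyz, 2, axis$anchor, `-`) %*% axis$direction
}

#' Estimate the parasternal long axis by PCA
#'
#' The long axis is the first principal component of the physical-mm
#' coordinates of all mask voxel centers: the eigenvector of their covariance
#' matrix with the largest eigenvalue, anchored at the mask centroid. The
#' eigenvector sign is arbitrary at this stage; use [orient_base_to_apex] to
#' orient it.
#'
#' @param lv_mask binary [volume_grid].
#' @return an (unoriented) [lv_axis].
#' @export
compute_plax <- function(lv_mask) {
  m <- as_binary_array(lv_mask, "LV mask")
  if (!any(m)) stop("empty mask: cannot estimate an axis")
  P <- voxel_centers(lv_mask, m)
  centroid <- colMeans(P)
  Pc <- sweep(P, 2, centroid)
  cv <- crossprod(Pc) / nrow(Pc)
  e <- eigen(cv, symmetric = TRUE)
  lam <- e$values
  if ((lam[1] - lam[2]) <= 1e-6 * lam[1])
    stop("ambiguous axis: the two largest principal variances are equal ",
         "within relative tolerance 1e-6")
  d <- e$vectors[, 1]
  t <- Pc %*% d
  lv_axis(centroid, d, min(t), max(t))
}

#' Orient an axis from base to apex
#'
#' PCA eigenvectors are sign-ambiguous. The apex is taken to be the extent
#' end with the smaller orthogonal cross-sectional mask area, estimated as
#' mask volume per unit axial length over the terminal 10% of
#' `[t_min, t_max]` at each end; the direction is negated if needed so it
#' points toward that end.
#'
#' @param axis an [lv_axis] from [compute_plax].
#' @param lv_mask the binary [volume_grid] the axis was computed from.
#' @param force `NULL` for the automatic rule; `"keep"` or `"flip"` to force
#'   the sign when the rule is ambiguous (terminal areas equal within 1%).
#' @return an [lv_axis] with `direction` pointing base to apex.
#' @export
orient_base_to_apex <- function(axis, lv_mask, force = NULL) {
  if (!is.null(force)) {
    force <- match.arg(force, c("keep", "flip"))
    return(if (force == "keep") axis else flip_axis(axis))
  }
  m <- as_binary_array(lv_mask, "LV mask")
  t <- axial_coord(axis, voxel_centers(lv_mask, m))
  band <- 0.1 * (axis$t_max - axis$t_min)
  vox_vol <- prod(grid_spacing(lv_mask))
  area_lo <- sum(t <= axis$t_min + band) * vox_vol / band
  area_hi <- sum(t >= axis$t_max - band) * vox_vol / band
  if (abs(area_lo - area_hi) <= 0.01 * max(area_lo, area_hi))
    stop("orientation-ambiguous: terminal cross-sections are equal within 1%; ",
         "pass force = \"keep\" or \"flip\"")
  if (area_hi < area_lo) axis else flip_axis(axis)
}

flip_axis <- function(axis) {
  lv_axis(axis$anchor, -axis$direction, -axis$t_max, -axis$t_min)
}

#' Angle between two undirected lines
#'
#' `acos(|d1 . d2|)` in degrees, folded to `[0, 90]`; invariant to negating
#' either direction.
#'
#' @param d1,d2 length-3 direction vectors (need not be normalized).
#' @return angle in degrees.
#' @export
angle_between_lines <- function(d1, d2) {
  n1 <- sqrt(sum(d1^2)); n2 <- sqrt(sum(d2^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("zero-length direction vector")
  acos(min(1, abs(sum(d1 * d2)) / (n1 * n2))) * 180 / pi
}

point_line_distance <- function(xyz, axis) {
  v <- sweep(matrix(xyz, ncol = 3), 2, axis$anchor)
  t <- v %*% axis$direction
  sqrt(pmax(rowSums(v^2) - t^2, 0))
}

#' Mean distance between two axis segments
#'
#' Symmetric sampled mean: points are placed every `step_mm` along each
#' segment within its own extent; each sample's Euclidean distance to the
#' other *infinite* line is taken, and the two directed means are averaged.
#'
#' @param segA,segB [lv_axis] objects with finite extents.
#' @param step_mm sampling step along each segment, mm (default 1).
#' @return mean distance in mm.
#' @export
line_mean_distance <- function(segA, segB, step_mm = 1) {
  stopifnot(step_mm > 0)
  directed <- function(a, b) {
    len <- a$t_max - a$t_min
    if (len <= 0) stop("zero-length segment")
    ts <- seq(a$t_min, a$t_max, by = step_mm)
    pts <- outer(ts, a$direction) + rep(a$anchor, each = length(ts))
    mean(point_line_distance(pts, b))
  }
  (directed(segA, segB) + directed(segB, segA)) / 2
}

#' Azimuth of a point about an axis
#'
#' Signed angle, in degrees wrapped to `[0, 360)`, from `ref_dir` to the
#' orthogonal component of `p - (axial projection of p)`, measured by the
#' right-hand rule about `axis$direction`.
#'
#' @param p n x 3 matrix (or length-3 vector) of mm points.
#' @param axis an [lv_axis].
#' @param ref_dir unit vector orthogonal to the axis direction (within 1e-6),
#'   defining azimuth 0.
#' @return numeric vector of azimuths in `[0, 360)`.
#' @export
azimuth_about_axis <- function(p, axis, ref_dir) {
  ref_dir <- ref_dir / sqrt(sum(ref_dir^2))
  if (abs(sum(ref_dir * axis$direction)) > 1e-6)
    stop("ref_dir must be orthogonal to the axis direction")
  e2 <- cross3(axis$direction, ref_dir)
  v <- sweep(matrix(p, ncol = 3), 2, axis$anchor)
  t <- as.vector(v %*% axis$direction)
  v <- v - outer(t, axis$direction)
  r <- sqrt(rowSums(v^2))
  if (any(r <= 1e-6))
    stop("undefined azimuth: point lies on the axis")
  th <- atan2(v %*% e2, v %*% ref_dir) * 180 / pi
  as.vector((th + 360) %% 360)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Compare a physician-drawn axis with a computed axis
#'
#' Combines [line_mean_distance] and [angle_between_lines] into the two
#' agreement measures reported for long-axis validation.
#'
#' @param physician,pca [lv_axis] objects.
#' @param step_mm sampling step for the mean distance, mm.
#' @return an object of class `axis_comparison` with `mean_distance_mm` and
#'   `angle_deg`.
#' @export
compare_axes <- function(physician, pca, step_mm = 1) {
  structure(list(
    mean_distance_mm = line_mean_distance(physician, pca, step_mm = step_mm),
    angle_deg = angle_between_lines(physician$direction, pca$direction)
  ), class = "axis_comparison")
}

#' @export
print.axis_comparison <- function(x, ...) {
  cat(sprintf("<axis_comparison> mean distance %.3f mm, angle %.3f deg\n",
              x$mean_distance_mm, x$angle_deg))
  invisible(x)
}
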