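# AHA 17-segment sectorization. Azimuth 0 is the RV-insertion direction;
# positive azimuth (right-hand rule about the base->apex direction) runs
# anterior -> anterolateral -> ... -> anteroseptal, which makes the apical
# anterior segment [-15, 75) concentric with the basal/mid anterior sector
# [0, 60). Angular and axial intervals are closed-left/open-right (final
# axial interval closed), with a 1e-9 nudge so voxels exactly on a boundary
# classify deterministically and stably under rigid motion.

EPS_ANG <- 1e-9
EPS_AX <- 1e-9

# label order with increasing azimuth from the RV reference
BASAL_ORDER  <- c(1L, 6L, 5L, 4L, 3L, 2L)
MID_ORDER    <- c(7L, 12L, 11L, 10L, 9L, 8L)
APICAL_ORDER <- c(13L, 16L, 15L, 14L)

#' AHA 17-segment lookup table
#'
#' @param scheme optionally a [sector_scheme]; when supplied, the table
#'   reflects its rotation sense (angular bounds are always reported in the
#'   scheme's own azimuth convention).
#' @return data.frame with `label`, `name`, `region`, `theta_lo`, `theta_hi`
#'   (degrees from the RV-insertion reference; NA for the apex cap).
#' @export
aha_segment_table <- function(scheme = NULL) {
  nm <- c("basal anterior", "basal anteroseptal", "basal inferoseptal",
          "basal inferior", "basal inferolateral", "basal anterolateral",
          "mid anterior", "mid anteroseptal", "mid inferoseptal",
          "mid inferior", "mid inferolateral", "mid anterolateral",
          "apical anterior", "apical septal", "apical inferior",
          "apical lateral", "apex")
  region <- c(rep("basal", 6), rep("mid", 6), rep("apical", 4), "apex")
  lo <- hi <- rep(NA_real_, 17)
  lo[BASAL_ORDER] <- 60 * (0:5);  hi[BASAL_ORDER] <- 60 * (1:6)
  lo[MID_ORDER] <- 60 * (0:5);    hi[MID_ORDER] <- 60 * (1:6)
  lo[APICAL_ORDER] <- -15 + 90 * (0:3)
  hi[APICAL_ORDER] <- -15 + 90 * (1:4)
  data.frame(label = 1:17, name = nm, region = region,
             theta_lo = lo, theta_hi = hi)
}

#' Azimuthal sector scheme anchored at the RV insertion
#'
#' Basal and mid rings are split into six 60-degree sectors with boundaries
#' at `{0, 60, ..., 300}` degrees from the RV-insertion reference direction;
#' the apical ring into four 90-degree sectors with boundaries at
#' `{-15, 75, 165, 255}` degrees.
#'
#' @param ref_dir unit 3-vector orthogonal to the long axis, pointing toward
#'   the RV insertion (azimuth 0).
#' @param flip_rotation reverse the azimuthal chirality (for anatomies whose
#'   handedness disagrees with the default right-hand convention).
#' @return object of class `sector_scheme`.
#' @export
sector_scheme <- function(ref_dir, flip_rotation = FALSE) {
  structure(list(
    ref_dir = ref_dir / sqrt(sum(ref_dir^2)),
    flip_rotation = isTRUE(flip_rotation),
    basal_mid_boundaries = 60 * (0:5),
    apical_boundaries = c(-15, 75, 165, 255),
    table = aha_segment_table()
  ), class = "sector_scheme")
}

#' Sector label for (region, azimuth)
#'
#' Total function after wrapping: any real `theta` is reduced mod 360.
#' Vectorized over `theta`.
#'
#' @param region one of `"basal"`, `"mid"`, `"apical"`, `"apex"` (scalar).
#' @param theta azimuth(s), degrees from the RV reference.
#' @param scheme a [sector_scheme] (only the label order matters here).
#' @return integer AHA label(s) in 1..17.
#' @export
sector_label <- function(region, theta, scheme = NULL) {
  region <- match.arg(region, c("basal", "mid", "apical", "apex"))
  if (region == "apex") return(rep(17L, length(theta)))
  th <- theta %% 360
  if (region %in% c("basal", "mid")) {
    k <- floor((th + EPS_ANG) / 60) %% 6
    ord <- if (region == "basal") BASAL_ORDER else MID_ORDER
    ord[k + 1]
  } else {
    j <- floor((((th + 15) %% 360) + EPS_ANG) / 90) %% 4
    APICAL_ORDER[j + 1]
  }
}

#' Short-axis region planes along the long axis
#'
#' Splits the shell into basal, mid-cavitary, apical and apex regions. The
#' basal extent `t0` and apex tip `t4` are the min/max axial coordinates of
#' shell voxels. The apex starts at `t3`: under the default `cavity_tip`
#' rule the maximal axial coordinate of cavity voxels (the "no-cavity cap"
#' convention), or `t0 + (1 - f) * (t4 - t0)` for a numeric fraction `f`.
#' `t1`, `t2` trisect `[t0, t3]` so the three named regions have equal
#' axial span.
#'
#' @param myoset a [make_myocardium] result (basal cap possibly removed).
#' @param axis an [lv_axis] oriented base to apex.
#' @param apex_rule `"cavity_tip"` or a fraction in (0, 1).
#' @return object of class `region_planes` with fields `t0`..`t4` (mm).
#' @export
region_planes <- function(myoset, axis, apex_rule = "cavity_tip") {
  myo <- myoset$myo$data != 0
  if (!any(myo)) stop("empty myocardium")
  t <- axial_coord(axis, voxel_centers(myoset$myo, myo))
  t0 <- min(t); t4 <- max(t)
  if (identical(apex_rule, "cavity_tip")) {
    cav <- myoset$cavity$data != 0
    if (!any(cav))
      stop("cavity is empty: the cavity_tip apex rule needs a nonempty cavity")
    t3 <- max(axial_coord(axis, voxel_centers(myoset$cavity, cav)))
  } else if (is.numeric(apex_rule) && length(apex_rule) == 1 &&
             apex_rule > 0 && apex_rule < 1) {
    t3 <- t0 + (1 - apex_rule) * (t4 - t0)
  } else {
    stop("apex_rule must be \"cavity_tip\" or a fraction in (0, 1)")
  }
  if (t3 <= t0) stop("degenerate region planes: t3 <= t0")
  t3 <- min(t3, t4)
  structure(list(t0 = t0, t1 = t0 + (t3 - t0) / 3,
                 t2 = t0 + 2 * (t3 - t0) / 3, t3 = t3, t4 = t4),
            class = "region_planes")
}

#' @export
print.region_planes <- function(x, ...) {
  cat(sprintf("<region_planes> t0..t4 = %.2f | %.2f | %.2f | %.2f | %.2f mm\n",
              x$t0, x$t1, x$t2, x$t3, x$t4))
  invisible(x)
}

region_index <- function(t, planes) {
  1L + (t + EPS_AX >= planes$t1) + (t + EPS_AX >= planes$t2) +
    (t + EPS_AX >= planes$t3)
}

REGION_NAMES <- c("basal", "mid", "apical", "apex")

#' Assign AHA segment labels to shell voxels
#'
#' The azimuth reference is the orthogonal component of
#' `rv_point - (its projection on the axis)`; every shell voxel is labeled
#' by its region (axial coordinate against `planes`) and azimuth (against
#' `scheme`). Nonzero labels exactly partition the shell.
#'
#' @param myoset a [make_myocardium] result.
#' @param axis an [lv_axis] oriented base to apex.
#' @param rv_point length-3 RV-insertion point, mm. Must be off-axis; only
#'   its azimuth matters (an axial position outside the extent is clamped
#'   with a warning).
#' @param planes a [region_planes]; computed with defaults when NULL.
#' @param scheme a [sector_scheme]; built from `rv_point` when NULL.
#' @param flip_rotation used only when `scheme` is NULL.
#' @return object of class `segmentation_result` with fields `labels`,
#'   `myo` ([volume_grid]s), `axis`, `planes`, `scheme`, `mode`, `config`,
#'   `warnings`.
#' @export
assign_segments <- function(myoset, axis, rv_point, planes = NULL,
                            scheme = NULL, flip_rotation = FALSE) {
  rv_point <- as.numeric(rv_point)
  stopifnot(length(rv_point) == 3)
  warnings <- character()
  t_rv <- as.numeric(axial_coord(axis, rv_point))
  v <- rv_point - axis$anchor - t_rv * axis$direction
  if (sqrt(sum(v^2)) <= 1e-6)
    stop("rv_point lies on the long axis: azimuth reference undefined")
  if (is.null(planes)) planes <- region_planes(myoset, axis)
  if (t_rv < planes$t0 || t_rv > planes$t4) {
    warnings <- c(warnings, sprintf(
      "rv_point projects outside the axial extent (t = %.2f); clamped", t_rv))
    warning(warnings[length(warnings)])
  }
  if (is.null(scheme))
    scheme <- sector_scheme(v, flip_rotation = flip_rotation)

  myo <- myoset$myo$data != 0
  P <- voxel_centers(myoset$myo, myo)
  t <- as.vector(axial_coord(axis, P))
  th <- azimuth_about_axis(P, axis, scheme$ref_dir)
  if (scheme$flip_rotation) th <- (360 - th) %% 360

  reg <- region_index(t, planes)
  lab <- integer(length(t))
  for (r in 1:4) {
    sel <- reg == r
    if (any(sel)) lab[sel] <- sector_label(REGION_NAMES[r], th[sel], scheme)
  }
  labels <- array(0L, dim(myo))
  labels[myo] <- lab

  missing <- setdiff(1:17, unique(lab))
  if (length(missing) > 0) {
    warnings <- c(warnings, paste("segments with zero voxels:",
                                  paste(missing, collapse = ", ")))
    warning(warnings[length(warnings)])
  }
  structure(list(
    labels = volume_grid(labels, myoset$myo$affine),
    myo = myoset$myo, axis = axis, planes = planes, scheme = scheme,
    mode = "voxel", config = NULL, warnings = warnings
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  labs <- x$labels$data
  cat(sprintf("<segmentation_result> mode %s, %d labeled voxels, %d distinct segments\n",
              x$mode, sum(labs != 0), length(setdiff(unique(as.vector(labs)), 0))))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Morphological closing of each segment
#'
#' Each segment's binary mask is closed with a Euclidean ball of
#' `radius_mm` and re-intersected with the shell. To keep the output a
#' partition of the shell, voxels claimed by several closed segments, or by
#' none, keep their pre-closing label.
#'
#' @param result a voxel-mode [assign_segments]/[run_asset] result.
#' @param radius_mm ball radius, mm (0 is the identity).
#' @return the result with `labels` replaced.
#' @export
close_segments <- function(result, radius_mm = 2) {
  stopifnot(radius_mm >= 0)
  if (radius_mm == 0) return(result)
  labs <- result$labels$data
  myo <- result$myo$data != 0
  sp <- grid_spacing(result$labels)
  claims <- array(0L, dim(labs))
  winner <- array(0L, dim(labs))
  for (l in setdiff(sort(unique(as.vector(labs))), 0L)) {
    cl <- binary_close_mm(labs == l, sp, radius_mm) & myo
    claims <- claims + cl
    winner[cl] <- ifelse(claims[cl] == 1L, l, winner[cl])
  }
  once <- myo & claims == 1L
  out <- labs
  out[once] <- winner[once]
  result$labels$data <- out
  result
}
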