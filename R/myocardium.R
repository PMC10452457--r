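#' Construct the myocardial shell from an LV mask
#'
#' The myocardium is standardized to a fixed wall thickness (default 8 mm):
#' the cavity is the morphological erosion of the LV mask by a Euclidean
#' ball of `thickness_mm`, computed as the set of mask voxels whose distance
#' transform to background is at least `thickness_mm` (anisotropy-aware, in
#' mm), and the shell is the mask minus the cavity. This is used when image
#' contrast cannot resolve the endocardium; a curated LV mask whose blood
#' pool reaches the image edge (e.g. cropped at the mitral-valve plane)
#' keeps an open base, since no background lies beyond the array there.
#'
#' @param lv_mask binary [volume_grid].
#' @param thickness_mm wall thickness in mm (> 0), default 8.
#' @return an object of class `myocardium_set`: `myo` and `cavity`
#'   ([volume_grid]s), `thickness_mm`, and `warnings` (character; notes an
#'   empty cavity when the thickness swallows the whole mask).
#' @export
make_myocardium <- function(lv_mask, thickness_mm = 8) {
  if (thickness_mm <= 0) stop("thickness_mm must be positive")
  m <- as_binary_array(lv_mask, "LV mask")
  if (!any(m)) stop("empty LV mask")
  dist_bg <- distance_transform_mm(!m, grid_spacing(lv_mask))
  cavity <- m & (dist_bg >= thickness_mm)
  myo <- m & !cavity
  warnings <- character()
  if (!any(cavity)) {
    warnings <- "cavity is empty: thickness_mm exceeds the mask's inner radius"
    warning(warnings)
  }
  structure(list(
    myo = volume_grid(array(as.integer(myo), dim(m)), lv_mask$affine),
    cavity = volume_grid(array(as.integer(cavity), dim(m)), lv_mask$affine),
    thickness_mm = thickness_mm,
    basal_cut_t = NULL,
    warnings = warnings
  ), class = "myocardium_set")
}

#' @export
print.myocardium_set <- function(x, ...) {
  cat(sprintf("<myocardium_set> thickness %.1f mm, %d shell / %d cavity voxels\n",
              x$thickness_mm, sum(x$myo$data != 0), sum(x$cavity$data != 0)))
  invisible(x)
}

#' Wall thickness along a ray
#'
#' Marches from `origin` along `direction` in small steps, looks up the
#' voxel containing each sample, and returns the radial distance between the
#' outermost shell sample and the outermost cavity sample: the apparent wall
#' thickness along that ray. Used to verify the inner-ring construction.
#'
#' @param myoset a [make_myocardium] result.
#' @param origin ray origin, mm (typically the cavity center).
#' @param direction length-3 ray direction (normalized internally).
#' @param r_max maximal ray length, mm.
#' @param step_mm march step, mm (default 0.05).
#' @return thickness in mm, or `NA` if the ray misses shell or cavity.
#' @export
ray_wall_thickness <- function(myoset, origin, direction, r_max,
                               step_mm = 0.05) {
  d <- direction / sqrt(sum(direction^2))
  r <- seq(0, r_max, by = step_mm)
  pts <- outer(r, d) + rep(origin, each = length(r))
  ijk <- round(world_to_voxel(myoset$myo, pts)) + 1
  dm <- dim(myoset$myo$data)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dm[1] & ijk[, 2] >= 1 & ijk[, 2] <= dm[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= dm[3]
  lin <- ijk[ok, 1] + dm[1] * (ijk[ok, 2] - 1) + dm[1] * dm[2] * (ijk[ok, 3] - 1)
  in_myo <- myoset$myo$data[lin] != 0
  in_cav <- myoset$cavity$data[lin] != 0
  if (!any(in_myo) || !any(in_cav)) return(NA_real_)
  rr <- r[ok]
  max(rr[in_myo]) - max(rr[in_cav])
}

#' Remove the basal cap of the myocardium
#'
#' Automatable analogue of the manual removal of the mitral-valve region:
#' shell voxels whose axial coordinate lies below `t_base` (toward the base)
#' are discarded by a plane cut perpendicular to the long axis, producing
#' the conical shell. The cavity is untouched; `t_base` is recorded for
#' provenance.
#'
#' @param myoset a [make_myocardium] result.
#' @param axis an [lv_axis] oriented base to apex.
#' @param t_base axial coordinate of the cut plane, within
#'   `[axis$t_min, axis$t_max]`.
#' @return the modified `myocardium_set`.
#' @export
remove_basal_cap <- function(myoset, axis, t_base) {
  if (t_base < axis$t_min || t_base > axis$t_max)
    stop(sprintf("t_base %.2f outside the axial extent [%.2f, %.2f]",
                 t_base, axis$t_min, axis$t_max))
  myo <- myoset$myo$data != 0
  if (any(myo)) {
    t <- axial_coord(axis, voxel_centers(myoset$myo, myo))
    drop <- which(myo)[t < t_base]
    myo[drop] <- FALSE
  }
  myoset$myo$data <- array(as.integer(myo), dim(myo))
  myoset$basal_cut_t <- t_base
  myoset
}
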