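#' Pipeline configuration
#'
#' @param thickness_mm myocardial wall thickness for the inner-ring erosion,
#'   mm (default 8).
#' @param apex_rule `"cavity_tip"` (apex = shell distal to the endocardial
#'   cavity tip, the default) or a fraction in (0, 1) of the axial extent.
#' @param closing_radius_mm structuring-ball radius for per-segment closing
#'   in voxel mode, mm; 0 disables closing (default 2).
#' @param mode `"voxel"` (every shell voxel labeled directly) or
#'   `"surface_closing"` (labels assigned only on endocardial/epicardial
#'   boundary voxels, then propagated through the wall by morphological
#'   closing).
#' @param flip_rotation reverse the azimuthal chirality.
#' @param basal_cut optional axial coordinate at which [remove_basal_cap]
#'   truncates the shell; NULL (default) assumes a curated input.
#' @param mda_step_mm sampling step for axis mean-distance comparisons, mm.
#' @param surface_closing_radius_mm ball radius for surface mode; NULL
#'   (default) auto-selects `thickness_mm / 2` plus half a voxel diagonal so
#'   closing bridges the wall between the two labeled surfaces.
#' @param force_orientation NULL, `"keep"` or `"flip"`, passed to
#'   [orient_base_to_apex] for masks whose terminal cross-sections tie.
#' @return a list of class `asset_config`.
#' @export
asset_config <- function(thickness_mm = 8, apex_rule = "cavity_tip",
                         closing_radius_mm = 2, mode = c("voxel", "surface_closing"),
                         flip_rotation = FALSE, basal_cut = NULL,
                         mda_step_mm = 1, surface_closing_radius_mm = NULL,
                         force_orientation = NULL) {
  stopifnot(thickness_mm > 0, closing_radius_mm >= 0, mda_step_mm > 0)
  structure(list(
    thickness_mm = thickness_mm, apex_rule = apex_rule,
    closing_radius_mm = closing_radius_mm, mode = match.arg(mode),
    flip_rotation = isTRUE(flip_rotation), basal_cut = basal_cut,
    mda_step_mm = mda_step_mm,
    surface_closing_radius_mm = surface_closing_radius_mm,
    force_orientation = force_orientation
  ), class = "asset_config")
}

#' Run the full 17-segment pipeline
#'
#' End-to-end automatic segmentation: PCA long axis, base-to-apex
#' orientation, inner-ring myocardium, optional basal-plane cut, equal-span
#' region planes, RV-anchored sectorization, and morphological-closing
#' post-processing.
#'
#' @param lv_mask binary LV [volume_grid].
#' @param rv_point length-3 RV-insertion point, physical mm.
#' @param config an [asset_config].
#' @return a `segmentation_result`; `$labels` is a 0-17 [volume_grid],
#'   nonzero exactly on the shell in voxel mode, with the axis, planes,
#'   scheme, config snapshot and accumulated warnings attached.
#' @export
run_asset <- function(lv_mask, rv_point, config = asset_config()) {
  stopifnot(inherits(config, "asset_config"))
  axis <- compute_plax(lv_mask)
  axis <- orient_base_to_apex(axis, lv_mask, force = config$force_orientation)
  myoset <- make_myocardium(lv_mask, thickness_mm = config$thickness_mm)
  if (!is.null(config$basal_cut))
    myoset <- remove_basal_cap(myoset, axis, config$basal_cut)
  planes <- region_planes(myoset, axis, apex_rule = config$apex_rule)
  res <- assign_segments(myoset, axis, rv_point, planes = planes,
                         flip_rotation = config$flip_rotation)
  res$warnings <- c(myoset$warnings, res$warnings)
  if (config$mode == "voxel") {
    if (config$closing_radius_mm > 0)
      res <- close_segments(res, config$closing_radius_mm)
  } else {
    res <- surface_closing_labels(res, config)
  }
  res$config <- config
  res
}

# Surface-assignment variant: keep labels only on the endocardial and
# epicardial boundary voxels of the shell, then recover full-wall segments by
# closing each label with a ball large enough to bridge the wall. Voxels
# claimed by several closed labels go to the nearest labeled surface voxel
# (Euclidean, mm); shell voxels no closed label reaches (mid-wall wedges at
# sector boundaries, where the ball crosses into the neighbor's territory)
# are likewise assigned to the nearest labeled surface voxel, so the output
# remains a partition of the shell.
surface_closing_labels <- function(res, config) {
  labs <- res$labels$data
  myo <- res$myo$data != 0
  sp <- grid_spacing(res$labels)
  r <- config$surface_closing_radius_mm
  if (is.null(r)) r <- config$thickness_mm / 2 + sqrt(sum(sp^2)) / 2

  surf <- boundary_voxels(myo)
  labs[!surf] <- 0L

  claim_lab <- array(0L, dim(labs)); claim_d <- array(Inf, dim(labs))
  near_lab <- array(0L, dim(labs));  near_d <- array(Inf, dim(labs))
  claims <- array(0L, dim(labs))
  for (l in setdiff(sort(unique(as.vector(labs))), 0L)) {
    sel <- labs == l
    cl <- binary_close_mm(sel, sp, r) & myo
    claims <- claims + cl
    dl <- distance_transform_mm(sel, sp)
    take <- cl & (dl < claim_d)
    claim_lab[take] <- l; claim_d[take] <- dl[take]
    upd <- myo & (dl < near_d)
    near_lab[upd] <- l; near_d[upd] <- dl[upd]
  }
  out <- array(0L, dim(labs))
  claimed <- claims > 0L
  out[claimed] <- claim_lab[claimed]
  fill <- myo & !claimed
  out[fill] <- near_lab[fill]
  if (any(fill)) {
    res$warnings <- c(res$warnings, sprintf(
      "%d shell voxels unreached by surface closing were assigned to the nearest labeled surface",
      sum(fill)))
  }
  res$labels$data <- out
  res$mode <- "surface_closing"
  res
}

#' Sidecar segment table for a result
#'
#' @param result a `segmentation_result`.
#' @return data.frame: label, AHA name, region, angular interval, voxel
#'   count.
#' @export
segment_report_table <- function(result) {
  tab <- aha_segment_table(result$scheme)
  tab$voxels <- vapply(tab$label, function(l) sum(result$labels$data == l),
                       integer(1))
  tab
}
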