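#' Centre of volume of a structure
#'
#' Unweighted centroid of the occupied voxel centres, in mm. The per-phase
#' GTV centre-of-volume trajectory is the basis of the motion
#' quantification and of the tracking isocenter shift.
#'
#' @inheritParams expand_margin
#' @return Numeric length-3 vector (x, y, z) in mm.
#' @export
center_of_volume <- function(mask, grid = NULL) {
  m <- as_rt_mask(mask, grid)
  idx <- which(m$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty-structure error: mask has no voxels")
  c(
    x = mean(axis_coords(m$grid, 1)[idx[, 1]]),
    y = mean(axis_coords(m$grid, 2)[idx[, 2]]),
    z = mean(axis_coords(m$grid, 3)[idx[, 3]])
  )
}

#' 3-D motion magnitude from per-axis amplitudes
#'
#' Euclidean norm of the three directional amplitudes,
#' `sqrt(AP^2 + SI^2 + LR^2)` (mm). Permutation-invariant and bounded by
#' `max(component) <= result <= sum(components)`.
#'
#' @param ap,si,lr Non-negative per-axis maximal displacements (mm).
#' @return Scalar 3-D motion (mm).
#' @export
motion_3d <- function(ap, si, lr) {
  if (any(c(ap, si, lr) < 0)) stop("domain error: amplitudes must be >= 0")
  sqrt(ap^2 + si^2 + lr^2)
}

#' Per-axis motion amplitudes of a centre-of-volume trajectory
#'
#' The tumor motion per direction is the maximal displacement over the
#' breathing cycle, implemented as the peak-to-peak range (max - min) of
#' the trajectory per axis, mapped to the AP (y), SI (z) and LR (x) axes.
#'
#' @param cov_trajectory n x 3 matrix of (x, y, z) positions in mm
#'   (one row per breathing phase), e.g. `phantom$cov_trajectory`.
#' @return A one-row tibble with `ap_mm`, `si_mm`, `lr_mm` and the derived
#'   `motion3d_mm`.
#' @export
motion_amplitudes <- function(cov_trajectory) {
  m <- as.matrix(cov_trajectory)
  if (nrow(m) < 1) stop("motion_amplitudes: need at least one trajectory point")
  p2p <- apply(m, 2, function(v) diff(range(v)))
  tibble::tibble(
    ap_mm = p2p[2], si_mm = p2p[3], lr_mm = p2p[1],
    motion3d_mm = motion_3d(p2p[2], p2p[3], p2p[1])
  )
}

#' Motion envelope (union) of masks over breathing phases
#'
#' Voxel-wise logical OR of per-phase structure masks; applied to the GTV
#' this is the internal target volume (ITV). The envelope is a superset of
#' every input mask and its volume equals the per-phase volume only for
#' zero motion.
#'
#' @param masks List of `rt_mask` objects on a shared grid.
#' @return An `rt_mask`.
#' @export
union_envelope <- function(masks) {
  if (length(masks) < 1) stop("union_envelope: need at least one mask")
  g <- masks[[1]]$grid
  acc <- masks[[1]]$voxels
  for (m in masks[-1]) {
    stopifnot_same_grid(g, m$grid, "envelope masks")
    acc <- acc | m$voxels
  }
  rt_mask(acc, g, label = paste0(masks[[1]]$label, "_envelope"))
}

#' Relative PTV size change from ITV to tracking, signed percent
#'
#' Returns `-100 * (v_itv - v_track) / v_itv`: negative values mean the
#' tracking PTV is smaller (the sign convention of plotting PTV reduction
#' against tumor motion). Use the absolute value in prose summaries.
#'
#' @param v_itv ITV-concept PTV volume (> 0), any consistent unit.
#' @param v_track Tracking PTV volume, same unit.
#' @return Signed percent change.
#' @export
ptv_reduction_percent <- function(v_itv, v_track) {
  if (any(v_itv <= 0)) stop("domain error: v_itv must be positive")
  -100 * (v_itv - v_track) / v_itv
}

#' Build the planning structure set for one treatment arm
#'
#' For the ITV arm, the GTV and each organ at risk are replaced by their
#' motion envelopes over all phases, the ITV is expanded by the PTV margin,
#' and planning happens on the time-averaged anatomy. For the tracking arm
#' the reference ("contouring") phase structures are used directly and the
#' PTV is the reference GTV plus the same margin. OARs receive no margin.
#'
#' @param phantom A `four_d_phantom`.
#' @param arm `"itv"` or `"tracking"`.
#' @param margin_mm Target-to-PTV margin (default 5 mm).
#' @return An object of class `structure_set`: list with `arm`, `margin_mm`,
#'   `grid`, `masks` (named list: `target` (ITV or reference GTV), `ptv`,
#'   `gtv_ref`, and the OARs) and `planning_density`.
#' @export
build_structure_set <- function(phantom, arm = c("itv", "tracking"), margin_mm = 5) {
  arm <- match.arg(arm)
  grid <- phantom$phases[[1]]$grid
  ref <- phantom$reference_phase
  oar_names <- setdiff(names(phantom$phases[[ref]]$masks), c("body", "gtv"))
  masks <- list()
  if (arm == "itv") {
    itv <- union_envelope(lapply(phantom$phases, function(p) p$masks$gtv))
    itv$label <- "itv"
    masks$target <- itv
    masks$ptv <- expand_margin(itv, margin_mm)
    masks$ptv$label <- "ptv_itv"
    for (nm in oar_names) {
      env <- union_envelope(lapply(phantom$phases, function(p) p$masks[[nm]]))
      env$label <- nm
      masks[[nm]] <- env
    }
    planning_density <- average_geometry(phantom)$density
  } else {
    gtv <- phantom$phases[[ref]]$masks$gtv
    gtv$label <- "gtv_track"
    masks$target <- gtv
    masks$ptv <- expand_margin(gtv, margin_mm)
    masks$ptv$label <- "ptv_track"
    for (nm in oar_names) masks[[nm]] <- phantom$phases[[ref]]$masks[[nm]]
    planning_density <- phantom$phases[[ref]]$density
  }
  masks$gtv_ref <- phantom$phases[[ref]]$masks$gtv
  masks$body <- phantom$phases[[ref]]$masks$body
  structure(
    list(arm = arm, margin_mm = margin_mm, grid = grid, masks = masks,
         planning_density = planning_density,
         reference_phase = ref),
    class = "structure_set"
  )
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf(
    "<structure_set> arm '%s': target %.1f cm^3, PTV %.1f cm^3 (margin %g mm)\n",
    x$arm, volume_cc(x$masks$target), volume_cc(x$masks$ptv), x$margin_mm
  ))
  invisible(x)
}

#' Dice similarity of two masks
#'
#' @param a,b `rt_mask` objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot_same_grid(a$grid, b$grid, "masks")
  2 * sum(a$voxels & b$voxels) / (sum(a$voxels) + sum(b$voxels))
}

#' Propagate a mask along a displacement field
#'
#' Nearest-neighbour resampling of a reference-phase mask into a breathing
#' phase using the ground-truth field (pull-back convention: the phase-k
#' mask at `y` equals the reference mask at `y - u(y)`, the
#' small-deformation inverse).
#'
#' @param mask Reference-phase `rt_mask`.
#' @param field `displacement_field` reference -> phase.
#' @return `rt_mask` on the same grid.
#' @export
propagate_mask <- function(mask, field) {
  stopifnot_same_grid(mask$grid, field$grid, "mask and field")
  pts <- grid_coords(mask$grid)
  src <- pts - field_vectors(field, pts)
  vox <- nn_sample_logical(mask$voxels, mask$grid, src)
  rt_mask(array(vox, dim = mask$grid$shape), mask$grid, label = mask$label)
}
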