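#' Configuration of a synthetic 4-D anatomical phantom
#'
#' Describes the stand-in for a respiration-resolved (4DCT-like) image set:
#' a water-equivalent body with a gross tumor volume (GTV) and the abdominal
#' organs at risk that matter for pancreatic SBRT (duodenum, stomach, bowel,
#' kidneys, liver, spinal cord), breathing with rigid-dominant periodic
#' motion that is largest along the superior-inferior axis.
#'
#' @param grid_shape Voxel counts per axis (default 64^3).
#' @param spacing_mm Voxel size (default 2 mm isotropic).
#' @param motion_amplitude_mm Named peak-to-peak amplitudes in mm,
#'   `c(ap=, si=, lr=)`. Defaults to the mean amplitudes of the bundled
#'   reference cohort (AP 2.0, SI 4.8, LR 1.3).
#' @param breathing_period_s Breathing period in seconds (default 4).
#' @param n_phases Number of equal-duration breathing phases (default 10).
#' @param reference_phase Optional 1-based index of the reference
#'   ("contouring") phase. By default the phase whose tumor position is
#'   closest to the time-averaged position (mid-ventilation) is chosen.
#' @param deformation_mode `"rigid"` (spatially constant displacement) or
#'   `"rigid_plus_local"` (adds a smooth Gaussian-windowed perturbation near
#'   the diaphragm to exercise deformable warping).
#' @param organs Organ geometry list as produced by [default_organs()].
#' @param gtv_density Density of the tumor relative to water (default 1.0,
#'   i.e. no contrast; the body is water-equivalent density 1, air 0).
#' @param jitter_mm Standard deviation of the per-organ centre jitter drawn
#'   from the seed; 0 disables jitter (default 0).
#' @param seed Integer seed controlling jitter; the phantom is bit-identical
#'   under a fixed seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64),
                           spacing_mm = 2,
                           motion_amplitude_mm = c(ap = 2.0, si = 4.8, lr = 1.3),
                           breathing_period_s = 4,
                           n_phases = 10,
                           reference_phase = NULL,
                           deformation_mode = c("rigid", "rigid_plus_local"),
                           organs = default_organs(),
                           gtv_density = 1.0,
                           jitter_mm = 0,
                           seed = 1L) {
  deformation_mode <- match.arg(deformation_mode)
  amp <- motion_amplitude_mm
  if (is.null(names(amp)) || !all(c("ap", "si", "lr") %in% names(amp))) {
    names(amp) <- c("ap", "si", "lr")[seq_along(amp)]
  }
  amp <- amp[c("ap", "si", "lr")]
  if (n_phases < 2) stop("invalid-config error: n_phases must be >= 2")
  if (breathing_period_s <= 0) stop("invalid-config error: breathing_period_s must be positive")
  if (any(amp < 0)) stop("invalid-config error: amplitudes must be >= 0")
  if (any(rep_len(spacing_mm, 3) <= 0)) stop("invalid-config error: spacing must be positive")
  if (!is.null(reference_phase) &&
      (reference_phase < 1 || reference_phase > n_phases)) {
    stop("invalid-config error: reference_phase out of range")
  }
  structure(
    list(
      grid = voxel_grid(grid_shape, spacing_mm),
      motion_amplitude_mm = amp,
      breathing_period_s = breathing_period_s,
      n_phases = as.integer(n_phases),
      reference_phase = reference_phase,
      deformation_mode = deformation_mode,
      organs = organs,
      gtv_density = gtv_density,
      jitter_mm = jitter_mm,
      seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

#' Default organ geometry for the abdominal phantom
#'
#' Simple geometric primitives on a ~128 mm cube: an elliptic-cylinder body,
#' an ellipsoidal GTV at the pancreatic head position, a duodenal tube
#' running cranio-caudally at a configurable lateral gap from the tumor,
#' and ellipsoids for stomach, bowel, liver and both kidneys, plus a static
#' spinal-cord cylinder posteriorly. All abdominal organs ride along with
#' the respiratory displacement; body outline and cord are static.
#'
#' @param gtv_semi_axes_mm GTV ellipsoid semi-axes (x, y, z) in mm.
#' @param duodenum_gap_mm Surface-to-surface gap between the GTV and the
#'   duodenal tube along +x (default 8 mm; small values create the
#'   PTV-OAR overlap that makes ITV planning hard).
#' @param duodenum_radius_mm Radius of the duodenal tube (default 6 mm).
#' @param body_semi_axes_mm Semi-axes of the elliptic-cylinder body (x, y).
#' @return A named list of organ definitions.
#' @export
default_organs <- function(gtv_semi_axes_mm = c(14, 12, 14),
                           duodenum_gap_mm = 8,
                           duodenum_radius_mm = 6,
                           body_semi_axes_mm = c(58, 52)) {
  duo_x <- gtv_semi_axes_mm[1] + duodenum_gap_mm + duodenum_radius_mm
  list(
    body = list(type = "cylinder", center = c(0, 0), radius = NULL,
                semi_axes = body_semi_axes_mm, z_range = NULL, moves = FALSE),
    gtv = list(type = "ellipsoid", center = c(0, 0, 0),
               semi_axes = gtv_semi_axes_mm, moves = TRUE),
    duodenum = list(type = "cylinder", center = c(duo_x, 0),
                    radius = duodenum_radius_mm, z_range = c(-30, 30), moves = TRUE),
    stomach = list(type = "ellipsoid", center = c(-24, -26, 8),
                   semi_axes = c(16, 13, 18), moves = TRUE),
    bowel = list(type = "ellipsoid", center = c(-2, -24, -34),
                 semi_axes = c(30, 18, 16), moves = TRUE),
    liver = list(type = "ellipsoid", center = c(30, 6, 34),
                 semi_axes = c(22, 22, 18), moves = TRUE),
    kidney_l = list(type = "ellipsoid", center = c(33, 27, -16),
                    semi_axes = c(9, 11, 16), moves = TRUE),
    kidney_r = list(type = "ellipsoid", center = c(-33, 27, -16),
                    semi_axes = c(9, 11, 16), moves = TRUE),
    cord = list(type = "cylinder", center = c(0, 40), radius = 5,
                z_range = NULL, moves = FALSE)
  )
}

#' High-overlap planning scenario
#'
#' A packaged phantom configuration in which the duodenum lies close to
#' the tumor and the lateral motion component is large, so that the
#' motion-envelope PTV overlaps the duodenal envelope deeply while the
#' tracking PTV stays clear of it: the regime in which envelope-based
#' plans cannot satisfy every planning objective but tracking plans can.
#'
#' @param grid_shape,spacing_mm Grid geometry (defaults 64^3 at 2 mm).
#' @return A [phantom_config()].
#' @export
high_overlap_config <- function(grid_shape = c(64, 64, 64), spacing_mm = 2) {
  phantom_config(
    grid_shape = grid_shape, spacing_mm = spacing_mm,
    motion_amplitude_mm = c(ap = 3.0, si = 8.0, lr = 6.0),
    organs = default_organs(duodenum_gap_mm = 6),
    jitter_mm = 0, seed = 1L
  )
}

#' Normalized breathing displacement per phase
#'
#' Single-frequency cosine breathing sampled at the midpoints of
#' `n_phases` equal-duration phase bins:
#' `s(t) = (1 - cos(2*pi*t / period_s)) / 2`, so 0 corresponds to full
#' inhale and the maximum value to full exhale displacement. The values are
#' symmetric about the half-period.
#'
#' @param period_s Breathing period in seconds (> 0).
#' @param n_phases Number of phase bins (>= 2).
#' @return Numeric vector of length `n_phases` in `[0, 1]`, with attribute
#'   `"t_mid"` giving the bin-midpoint times (s).
#' @export
make_breathing_trace <- function(period_s, n_phases) {
  if (period_s <= 0) stop("invalid-config error: period_s must be positive")
  if (n_phases < 2) stop("invalid-config error: n_phases must be >= 2")
  t_mid <- (seq_len(n_phases) - 0.5) / n_phases * period_s
  s <- (1 - cos(2 * pi * t_mid / period_s)) / 2
  attr(s, "t_mid") <- t_mid
  s
}

# Peak-to-peak rescaled trace: s in [0,1] exactly, so that
# amplitude * (s_k - s_ref) has per-axis peak-to-peak equal to the
# configured amplitude. Degenerates to the raw trace when it is constant
# (n_phases = 2 samples both sit at 0.5 by cosine symmetry).
normalized_trace <- function(period_s, n_phases) {
  s <- make_breathing_trace(period_s, n_phases)
  rng <- range(s)
  if (diff(rng) < 1e-12) return(s)
  out <- (s - rng[1]) / diff(rng)
  attr(out, "t_mid") <- attr(s, "t_mid")
  out
}

# (ap, si, lr) amplitudes -> (x=LR, y=AP, z=SI) displacement vector scale
amp_xyz <- function(amp) c(amp[["lr"]], amp[["ap"]], amp[["si"]])

#' Generate a synthetic 4-D phantom
#'
#' Builds `n_phases` anatomical phases with known, invertible respiratory
#' motion: every moving organ is displaced by `amplitude * (s_k - s_ref)`
#' where `s` is the peak-to-peak-normalized breathing trace. Reference
#' ("contouring") phase structures are voxelized analytically; the other
#' phases' structures are produced by propagating the reference masks
#' along the ground-truth displacement fields (nearest-neighbour
#' resampling), the synthetic counterpart of registration-based structure
#' propagation — so applying [propagate_mask()] with a stored field
#' reproduces a phase mask exactly. The GTV centre-of-volume trajectory
#' therefore recovers the configured per-axis peak-to-peak amplitudes
#' within one voxel (displacements are quantized to the lattice).
#' Ground-truth fields replace deformable image registration downstream.
#' Density is 1.0 inside the body and 0 outside (optionally with tumor
#' contrast, see [phantom_config()]).
#'
#' @param config A [phantom_config()].
#' @return An object of class `four_d_phantom` with elements `phases`
#'   (each a `phantom_phase` carrying a density grid, structure masks and
#'   the GTV centre-of-volume), `fields` (one `displacement_field` per
#'   phase, reference -> phase, pull-back convention), `trace`
#'   (normalized), `reference_phase`, `cov_trajectory` and `config`.
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- config$grid
  organs <- config$organs
  if (config$jitter_mm > 0) {
    organs <- jitter_organs(organs, config$jitter_mm, config$seed)
  }
  s <- normalized_trace(config$breathing_period_s, config$n_phases)
  dvec <- amp_xyz(config$motion_amplitude_mm)

  ref <- config$reference_phase
  if (is.null(ref)) {
    ref <- which.min(abs(s - mean(s)))[1]
  }
  shifts <- lapply(seq_len(config$n_phases), function(k) dvec * (s[k] - s[ref]))

  local_par <- NULL
  if (config$deformation_mode == "rigid_plus_local") {
    # Gaussian-windowed extra SI displacement near the diaphragm (superior
    # body region), scaled to 30% of the SI amplitude.
    local_par <- list(center = c(15, 0, 44), sigma = 22,
                      gain = 0.3 * dvec[3])
  }

  ref_masks <- build_organ_masks(grid, organs, rep(0, 3))
  check_organs_in_grid(ref_masks, organs, grid)

  phases <- vector("list", config$n_phases)
  fields <- vector("list", config$n_phases)
  for (k in seq_len(config$n_phases)) {
    fields[[k]] <- displacement_field(
      grid, phase = k, shift = shifts[[k]],
      local = if (!is.null(local_par)) c(local_par, list(s_diff = s[k] - s[ref]))
    )
    masks <- if (k == ref) {
      ref_masks
    } else {
      warp_masks_to_phase(ref_masks, fields[[k]], organs)
    }
    density <- build_density(masks, config$gtv_density)
    if (!any(masks$gtv$voxels)) stop("geometry error: GTV mask is empty")
    phases[[k]] <- structure(
      list(density = density, masks = masks,
           gtv_cov = center_of_volume(masks$gtv), grid = grid),
      class = "phantom_phase"
    )
  }
  cov_traj <- do.call(rbind, lapply(phases, function(p) p$gtv_cov))
  colnames(cov_traj) <- c("x", "y", "z")
  structure(
    list(phases = phases, fields = fields, trace = s,
         reference_phase = ref, cov_trajectory = cov_traj,
         config = config, organs = organs),
    class = "four_d_phantom"
  )
}

#' @export
print.four_d_phantom <- function(x, ...) {
  amp <- x$config$motion_amplitude_mm
  cat(sprintf(
    "<four_d_phantom> %d phases, reference phase %d, amplitudes AP %.1f / SI %.1f / LR %.1f mm (%s)\n",
    length(x$phases), x$reference_phase, amp[["ap"]], amp[["si"]], amp[["lr"]],
    x$config$deformation_mode
  ))
  invisible(x)
}

jitter_organs <- function(organs, sd_mm, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  scale <- exp(stats::rnorm(1, 0, 0.15))          # GTV size factor ~ lognormal
  for (nm in names(organs)) {
    o <- organs[[nm]]
    if (nm == "body" || nm == "cord") next
    jit <- stats::rnorm(length(o$center), 0, sd_mm)
    organs[[nm]]$center <- o$center + jit
    if (nm == "gtv") organs[[nm]]$semi_axes <- o$semi_axes * scale
  }
  organs
}

build_organ_masks <- function(grid, organs, shift) {
  masks <- list()
  for (nm in names(organs)) {
    o <- organs[[nm]]
    sh <- if (isTRUE(o$moves)) shift else rep(0, 3)
    vox <- switch(o$type,
      ellipsoid = ellipsoid_voxels(grid, o$center + sh, o$semi_axes),
      cylinder = {
        if (is.null(o$radius)) {
          # elliptic cylinder (body)
          xs <- (axis_coords(grid, 1) - o$center[1] - sh[1]) / o$semi_axes[1]
          ys <- (axis_coords(grid, 2) - o$center[2] - sh[2]) / o$semi_axes[2]
          ax <- outer(xs^2, ys^2, "+") <= 1
          arr <- array(FALSE, dim = grid$shape)
          for (k in seq_len(grid$shape[3])) arr[, , k] <- ax
          arr
        } else {
          zr <- if (is.null(o$z_range)) NULL else o$z_range + sh[3]
          cylinder_voxels(grid, o$center + sh[1:2], o$radius, zr)
        }
      },
      stop(sprintf("unknown organ primitive '%s'", o$type))
    )
    masks[[nm]] <- rt_mask(vox, grid, label = nm)
  }
  # clip everything to the body
  for (nm in setdiff(names(masks), "body")) {
    masks[[nm]]$voxels <- masks[[nm]]$voxels & masks$body$voxels
  }
  masks
}

check_organs_in_grid <- function(masks, organs, grid) {
  lim_lo <- grid$origin
  lim_hi <- grid$origin + (grid$shape - 1) * grid$spacing
  for (nm in names(organs)) {
    o <- organs[[nm]]
    if (o$type == "ellipsoid") {
      if (any(o$center - o$semi_axes < lim_lo - grid$spacing) ||
          any(o$center + o$semi_axes > lim_hi + grid$spacing)) {
        stop(sprintf("geometry error: organ '%s' exceeds the grid", nm))
      }
    }
  }
  invisible(TRUE)
}

build_density <- function(masks, gtv_density) {
  density <- array(0, dim = dim(masks$body$voxels))
  density[masks$body$voxels] <- 1
  if (gtv_density != 1) density[masks$gtv$voxels] <- gtv_density
  density
}

warp_masks_to_phase <- function(ref_masks, field, organs) {
  grid <- ref_masks$body$grid
  pts <- grid_coords(grid)
  u <- field_vectors(field, pts)
  src <- pts - u                                  # small-deformation inverse
  masks <- ref_masks
  for (nm in names(ref_masks)) {
    if (!isTRUE(organs[[nm]]$moves)) next
    vox <- nn_sample_logical(ref_masks[[nm]]$voxels, grid, src)
    masks[[nm]] <- rt_mask(array(vox, dim = grid$shape), grid, label = nm)
  }
  masks
}

#' Ground-truth displacement field for one phase
#'
#' Vector field (mm) on the voxel grid mapping reference-phase coordinates
#' to phase-k coordinates (pull-back convention): a point at `x` in the
#' reference anatomy sits at `x + u(x)` in phase k. For rigid phantoms the
#' field is spatially constant; the reference phase's field is identically
#' zero.
#'
#' @param phantom A `four_d_phantom`.
#' @param phase_k 1-based phase index.
#' @return A `displacement_field`.
#' @export
displacement_to_phase <- function(phantom, phase_k) {
  if (phase_k < 1 || phase_k > length(phantom$fields)) {
    stop("range error: phase index out of range")
  }
  phantom$fields[[phase_k]]
}

displacement_field <- function(grid, phase, shift, local = NULL) {
  structure(
    list(grid = grid, phase = phase, shift = as.numeric(shift), local = local),
    class = "displacement_field"
  )
}

#' Evaluate a displacement field at physical points
#'
#' @param field A `displacement_field`.
#' @param pts n x 3 matrix of (x, y, z) mm.
#' @return n x 3 matrix of displacement vectors (mm).
#' @export
field_vectors <- function(field, pts) {
  u <- matrix(rep(field$shift, each = nrow(pts)), ncol = 3)
  if (!is.null(field$local)) {
    lp <- field$local
    r2 <- (pts[, 1] - lp$center[1])^2 + (pts[, 2] - lp$center[2])^2 +
      (pts[, 3] - lp$center[3])^2
    u[, 3] <- u[, 3] + lp$gain * lp$s_diff * exp(-r2 / (2 * lp$sigma^2))
  }
  u
}

is_zero_field <- function(field) {
  all(field$shift == 0) &&
    (is.null(field$local) || field$local$s_diff == 0 || field$local$gain == 0)
}

#' Time-averaged anatomy of a 4-D phantom
#'
#' Voxel-wise mean of the per-phase density grids, the analogue of the
#' "average" reconstruction of a respiration-resolved scan on which
#' motion-envelope (ITV) plans are computed. Carries no structure masks:
#' ITV-arm structures come from the motion envelopes.
#'
#' @param phantom A `four_d_phantom`.
#' @return A `phantom_phase` with `masks = NULL`.
#' @export
average_geometry <- function(phantom) {
  if (length(phantom$phases) < 1) stop("average_geometry: phantom has no phases")
  acc <- phantom$phases[[1]]$density
  for (k in seq_along(phantom$phases)[-1]) acc <- acc + phantom$phases[[k]]$density
  structure(
    list(density = acc / length(phantom$phases), masks = NULL,
         gtv_cov = NULL, grid = phantom$phases[[1]]$grid),
    class = "phantom_phase"
  )
}
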