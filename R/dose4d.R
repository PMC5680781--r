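#' Split an arc into angular segments assigned to breathing phases
#'
#' Assuming constant gantry speed and uniform monitor units per degree,
#' the arc is cut at every breathing-phase transition; each segment's
#' monitor-unit share is proportional to its angular extent (shares sum to
#' 1 over the arc) and its phase follows cyclically from `start_phase`.
#'
#' @param arc One row of [default_arcs()] (or a list with `start_deg`,
#'   `stop_deg`, `direction`).
#' @param gantry_speed_deg_s Gantry speed (deg/s, > 0).
#' @param breathing_period_s Breathing period (s, > 0).
#' @param n_phases Number of breathing phases (>= 2).
#' @param start_phase 1-based phase active when the arc starts.
#' @return Tibble of class `arc_segments`: `angle_from`, `angle_to`
#'   (signed gantry angles along the delivery direction), `t_from`, `t_to`
#'   (s), `phase`, `share`.
#' @export
segment_arc_by_phase <- function(arc, gantry_speed_deg_s, breathing_period_s,
                                 n_phases, start_phase = 1) {
  if (gantry_speed_deg_s <= 0 || breathing_period_s <= 0) {
    stop("invalid-config error: speed and period must be positive")
  }
  if (n_phases < 2) stop("invalid-config error: n_phases must be >= 2")
  extent <- abs(arc$stop_deg - arc$start_deg)
  duration <- extent / gantry_speed_deg_s
  dt <- breathing_period_s / n_phases
  bounds <- unique(c(seq(0, duration, by = dt), duration))
  t_from <- bounds[-length(bounds)]
  t_to <- bounds[-1]
  phase <- ((start_phase - 1 + floor(t_from / dt + 1e-9)) %% n_phases) + 1
  out <- tibble::tibble(
    angle_from = arc$start_deg + arc$direction * t_from * gantry_speed_deg_s,
    angle_to = arc$start_deg + arc$direction * t_to * gantry_speed_deg_s,
    t_from = t_from, t_to = t_to, phase = as.integer(phase),
    share = (t_to - t_from) / duration
  )
  class(out) <- c("arc_segments", class(out))
  out
}

# Per-(sampled angle, phase) monitor-unit weight matrix for one fraction.
# Rows follow plan$angles (both arcs, delivery order); each arc carries an
# MU fraction proportional to its angular extent. Entries of one angle sum
# to that angle's plan weight, so the matrix totals exactly 1.
angle_phase_weights <- function(plan, gantry_speed_deg_s, breathing_period_s,
                                n_phases, start_phase = 1) {
  W <- matrix(0, length(plan$angles), n_phases)
  extents <- abs(plan$arcs$stop_deg - plan$arcs$start_deg)
  arc_mu <- extents / sum(extents)
  offset <- 0L
  phase0 <- start_phase
  for (r in seq_len(nrow(plan$arcs))) {
    arc <- plan$arcs[r, ]
    segs <- segment_arc_by_phase(arc, gantry_speed_deg_s, breathing_period_s,
                                 n_phases, phase0)
    n_ang <- round(extents[r] / plan$step_deg)
    idx <- offset + seq_len(n_ang)
    # angle bin i covers signed path [ (i-1)*step, i*step ) along delivery
    lo <- (seq_len(n_ang) - 1) * plan$step_deg
    hi <- seq_len(n_ang) * plan$step_deg
    s_lo <- abs(segs$angle_from - arc$start_deg)
    s_hi <- abs(segs$angle_to - arc$start_deg)
    for (s in seq_len(nrow(segs))) {
      ovl <- pmax(0, pmin(hi, s_hi[s]) - pmax(lo, s_lo[s]))
      W[idx, segs$phase[s]] <- W[idx, segs$phase[s]] +
        arc_mu[r] * ovl / extents[r]
    }
    # next arc starts where this one left the breathing cycle
    dur <- extents[r] / gantry_speed_deg_s
    dt <- breathing_period_s / n_phases
    phase0 <- ((phase0 - 1 + floor(dur / dt + 1e-9)) %% n_phases) + 1
    offset <- offset + n_ang
  }
  W
}

#' Dose of a single arc segment on one breathing phase
#'
#' The sub-plan dose the 4-D calculation is built from: only the segment's
#' angular interval contributes, weighted by its monitor-unit share, and
#' computed on the phase's density grid. In tracking mode the isocenter
#' and apertures are rigidly shifted by the phase's GTV centre-of-volume
#' displacement relative to the reference phase; in ITV mode no shift is
#' applied.
#'
#' @param treatment An `rt_treatment` (see [plan_itv()]).
#' @param segment One row of [segment_arc_by_phase()] output.
#' @param phantom The `four_d_phantom`.
#' @param mode `"itv"` or `"tracking"`.
#' @param arc Index of the arc the segment belongs to (default 1).
#' @return A `dose_grid` on the segment's phase. The segment's
#'   monitor-unit weight is its share of the arc times the arc's share of
#'   the plan, so summing sub-doses over all segments of both arcs
#'   reconstitutes the full plan dose.
#' @export
phase_subdose <- function(treatment, segment, phantom,
                          mode = c("itv", "tracking"), arc = 1) {
  mode <- match.arg(mode)
  plan <- treatment$plan
  k <- segment$phase
  arcrow <- plan$arcs[arc, ]
  extents <- abs(plan$arcs$stop_deg - plan$arcs$start_deg)
  arc_mu <- extents[arc] / sum(extents)
  # delivery-path positions of the segment within its arc
  s_lo <- abs(segment$angle_from - arcrow$start_deg)
  s_hi <- abs(segment$angle_to - arcrow$start_deg)
  lo <- min(s_lo, s_hi); hi <- max(s_lo, s_hi)
  sel <- which(plan$arc_id == arcrow$arc)
  frac <- numeric(length(plan$angles))
  pos_lo <- (seq_along(sel) - 1) * plan$step_deg
  pos_hi <- seq_along(sel) * plan$step_deg
  frac[sel] <- pmax(0, pmin(pos_hi, hi) - pmax(pos_lo, lo)) / plan$step_deg
  idx <- which(frac > 0)
  if (length(idx) == 0) {
    return(dose_grid(array(0, dim = plan$grid$shape), plan$grid,
                     provenance = sprintf("subdose|phase%d|%s", k, mode)))
  }
  # plan$weights are per-plan (both arcs); restrict to this arc's share of
  # the segment: each sampled angle contributes its covered fraction
  w <- frac[idx] * arc_mu / length(sel)
  dens <- phantom$phases[[k]]$density
  eng <- make_dose_engine(dens, plan$grid, plan$beam)
  shift <- if (mode == "tracking") phase_shift_3d(phantom, k) else c(0, 0, 0)
  sub <- compute_arc_dose(plan, dens, engine = eng, angle_idx = idx,
                          weights = w, shift_mm = shift)
  sub$provenance <- sprintf("subdose|phase%d|%s", k, mode)
  sub
}

# GTV displacement of phase k relative to the reference phase: exact
# stored rigid shift, or the measured centre-of-volume difference for
# deformed phantoms.
phase_shift_3d <- function(phantom, k) {
  f <- phantom$fields[[k]]
  if (is.null(f$local)) f$shift
  else phantom$cov_trajectory[k, ] - phantom$cov_trajectory[phantom$reference_phase, ]
}

#' Warp a phase dose to the reference phase
#'
#' Pull-back trilinear interpolation along the ground-truth displacement
#' field: `D_ref(x) = D_phase(x + u(x))`; samples falling outside the grid
#' contribute zero. A zero field returns the input unchanged (exact
#' identity), so zero-motion accumulation is bitwise equal to the static
#' dose.
#'
#' @param phase_dose `dose_grid` on phase k.
#' @param displacement_field The reference -> phase `displacement_field`.
#' @return `dose_grid` on the reference phase.
#' @export
warp_dose_to_reference <- function(phase_dose, displacement_field) {
  stopifnot_same_grid(phase_dose$grid, displacement_field$grid,
                      "dose and displacement field")
  if (is_zero_field(displacement_field)) return(phase_dose)
  grid <- phase_dose$grid
  pts <- grid_coords(grid)
  u <- field_vectors(displacement_field, pts)
  vals <- trilinear_sample(phase_dose$values, grid, pts + u, outside = 0)
  dose_grid(array(pmax(vals, 0), dim = grid$shape), grid,
            provenance = paste0(phase_dose$provenance, "|warped"))
}

#' Accumulate the 4-D dose of a treatment over the breathing cycle
#'
#' The full 4-D dose calculation: each arc is split into angular segments
#' assigned to breathing phases, per-phase sub-doses are computed (with
#' the isocenter following the tumor in tracking mode), warped to the
#' reference phase along the ground-truth fields, and summed over both
#' arcs and all fractions. Fractions are identical deliveries except for
#' their starting breathing phase, which by default steps through
#' phases 1, 3, 5, 7, 9 to average interplay over the five fractions.
#'
#' @param treatment `rt_treatment` from [plan_itv()] or [plan_track()].
#' @param phantom The `four_d_phantom` the treatment was planned on.
#' @param mode `"itv"` or `"tracking"` (defaults to the treatment arm).
#' @param gantry_speed_deg_s Gantry speed; the default 3 deg/s delivers a
#'   full arc in 120 s.
#' @param start_phases 1-based starting phase per fraction.
#' @param keep_phases Keep the per-phase accumulated sub-doses (for
#'   diagnostics; memory-heavier).
#' @return An `accumulated_dose`: list with `dose` (a `dose_grid` on the
#'   reference phase, Gy over the full course), `phase_weights` (per-phase
#'   monitor-unit shares), `mode`, and optionally `phase_doses`.
#' @export
accumulate_4d <- function(treatment, phantom, mode = NULL,
                          gantry_speed_deg_s = 3,
                          start_phases = c(1, 3, 5, 7, 9),
                          keep_phases = FALSE) {
  if (is.null(mode)) mode <- if (treatment$arm == "itv") "itv" else "tracking"
  mode <- match.arg(mode, c("itv", "tracking"))
  plan <- treatment$plan
  grid <- plan$grid
  n_phases <- length(phantom$phases)
  period <- phantom$config$breathing_period_s
  # total per-(angle, phase) MU weights over all fractions (each fraction
  # carries an equal share of the course MU)
  W <- matrix(0, length(plan$angles), n_phases)
  for (p0 in start_phases) {
    W <- W + angle_phase_weights(plan, gantry_speed_deg_s, period,
                                 n_phases, p0) / length(start_phases)
  }
  nax <- prod(grid$shape[1:2]); nz <- grid$shape[3]
  # per-phase engines: phases share one engine when their densities match
  engines <- phase_engines(phantom, plan$beam)
  phase_mats <- vector("list", n_phases)
  if (mode == "itv") {
    # apertures are not shifted and (for a static body outline) per-angle
    # doses are phase-independent: compute each angle once, split by W
    for (ai in seq_along(plan$angles)) {
      ph <- which(W[ai, ] > 0)
      if (length(ph) == 0) next
      per_phase_same <- engines$shared
      if (per_phase_same) {
        M <- angle_dose_matrix(engines$list[[1]], plan$tmaps[[ai]], plan$bev,
                               plan$angles[ai])
        for (k in ph) {
          if (is.null(phase_mats[[k]])) phase_mats[[k]] <- matrix(0, nax, nz)
          phase_mats[[k]] <- phase_mats[[k]] + W[ai, k] * M
        }
      } else {
        for (k in ph) {
          M <- angle_dose_matrix(engines$list[[k]], plan$tmaps[[ai]], plan$bev,
                                 plan$angles[ai])
          if (is.null(phase_mats[[k]])) phase_mats[[k]] <- matrix(0, nax, nz)
          phase_mats[[k]] <- phase_mats[[k]] + W[ai, k] * M
        }
      }
    }
  } else {
    for (k in seq_len(n_phases)) {
      ph_idx <- which(W[, k] > 0)
      if (length(ph_idx) == 0) next
      d3 <- phase_shift_3d(phantom, k)
      acc <- matrix(0, nax, nz)
      for (ai in ph_idx) {
        fr <- bev_frame(plan$angles[ai])
        shift_uv <- c(d3[1] * fr[1] + d3[2] * fr[2], d3[3])
        acc <- acc + W[ai, k] *
          angle_dose_matrix(engines$list[[if (engines$shared) 1 else k]],
                            plan$tmaps[[ai]], plan$bev, plan$angles[ai],
                            shift_uv = shift_uv)
      }
      phase_mats[[k]] <- acc
    }
  }
  total <- array(0, dim = grid$shape)
  phase_doses <- if (keep_phases) vector("list", n_phases)
  for (k in seq_len(n_phases)) {
    if (is.null(phase_mats[[k]])) next
    sub <- dose_grid(array(plan$scale * phase_mats[[k]], dim = grid$shape),
                     grid, provenance = sprintf("4D|phase%d|%s", k, mode))
    w <- warp_dose_to_reference(sub, phantom$fields[[k]])
    total <- total + w$values
    if (keep_phases) phase_doses[[k]] <- w
  }
  structure(
    list(
      dose = dose_grid(total, grid,
                       provenance = paste0("4D-accumulated|", mode)),
      phase_weights = colSums(W), mode = mode,
      angle_phase_weights = W,
      phase_doses = phase_doses
    ),
    class = "accumulated_dose"
  )
}

phase_engines <- function(phantom, beam) {
  n <- length(phantom$phases)
  d1 <- phantom$phases[[1]]$density
  shared <- all(vapply(seq_len(n), function(k) {
    max(abs(phantom$phases[[k]]$density - d1)) == 0
  }, logical(1)))
  grid <- phantom$phases[[1]]$grid
  if (shared) {
    list(shared = TRUE, list = list(make_dose_engine(d1, grid, beam)))
  } else {
    list(shared = FALSE,
         list = lapply(phantom$phases, function(p) {
           make_dose_engine(p$density, grid, beam)
         }))
  }
}

#' @export
print.accumulated_dose <- function(x, ...) {
  cat(sprintf("<accumulated_dose> [%s] max %.2f Gy; phase MU shares: %s\n",
              x$mode, max(x$dose$values),
              paste(sprintf("%.3f", x$phase_weights), collapse = " ")))
  invisible(x)
}
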