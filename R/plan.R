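#' Two-arc conformal plan geometry
#'
#' @param step_deg Angular sampling step (degrees; must divide 360).
#' @return Tibble of arc specifications: two full arcs traversed in
#'   opposite directions, collimator angles 5 and 355 degrees (metadata
#'   only in this surrogate).
#' @export
default_arcs <- function(step_deg = 5) {
  if (360 %% step_deg != 0) stop("default_arcs: step must divide 360")
  tibble::tibble(
    arc = c(1L, 2L), start_deg = c(0, 360), stop_deg = c(360, 0),
    direction = c(1, -1), collimator_deg = c(5, 355), step_deg = step_deg
  )
}

#' Build a conformal arc plan for a target
#'
#' Per sampled gantry angle, the aperture is the beam's-eye-view projection
#' of the target dilated by `aperture_margin_mm`; monitor-unit weights are
#' uniform per degree (each sampled angle carries an equal share, summing
#' to 1 over both arcs). With the default zero aperture margin the PTV
#' surface sits in the middle of the penumbra; normalizing D95 of the PTV
#' to the prescription then escalates the target interior well above it,
#' emulating the dose heterogeneity of a peripheral (60% isodose)
#' prescription.
#'
#' @param target_mask `rt_mask` of the PTV to conform to.
#' @param beam A [beam_model()].
#' @param arcs Arc table from [default_arcs()].
#' @param aperture_margin_mm Aperture margin (mm, default 0).
#' @param isocenter Plan isocenter (mm); defaults to the target
#'   centre of volume.
#' @return An object of class `rt_plan`.
#' @export
make_arc_plan <- function(target_mask, beam = beam_model(), arcs = default_arcs(),
                          aperture_margin_mm = 0, isocenter = NULL) {
  grid <- target_mask$grid
  if (!any(target_mask$voxels)) stop("empty-structure error: target mask is empty")
  if (is.null(isocenter)) isocenter <- center_of_volume(target_mask)
  bev <- make_bev_grid(grid)
  step <- arcs$step_deg[1]
  angles <- numeric(0); arc_id <- integer(0)
  for (r in seq_len(nrow(arcs))) {
    n <- round(abs(arcs$stop_deg[r] - arcs$start_deg[r]) / step)
    centers <- arcs$start_deg[r] +
      arcs$direction[r] * (seq_len(n) - 0.5) * step
    angles <- c(angles, centers %% 360)
    arc_id <- c(arc_id, rep(arcs$arc[r], n))
  }
  weights <- rep(1 / length(angles), length(angles))
  # apertures depend only on the beam line (angle mod 180)
  uniq <- sort(unique(angles %% 180))
  ap_by_line <- lapply(uniq, function(th) {
    bev_aperture(target_mask, th, margin_mm = aperture_margin_mm, bev = bev)$aperture
  })
  names(ap_by_line) <- sprintf("%.4f", uniq)
  apertures <- lapply(angles, function(th) ap_by_line[[sprintf("%.4f", th %% 180)]])
  tmaps <- lapply(apertures, transmission_map, h = bev$h, dv = bev$dv,
                  sigma_mm = beam$sigma_mm)
  structure(
    list(angles = angles, arc_id = arc_id, weights = weights, step_deg = step,
         arcs = arcs, apertures = apertures, tmaps = tmaps, bev = bev,
         beam = beam, isocenter = isocenter, grid = grid, scale = 1,
         aperture_margin_mm = aperture_margin_mm),
    class = "rt_plan"
  )
}

#' @export
print.rt_plan <- function(x, ...) {
  cat(sprintf(
    "<rt_plan> %d arcs, %d sampled angles (step %g deg), scale %.4g Gy/weight\n",
    nrow(x$arcs), length(x$angles), x$step_deg, x$scale
  ))
  invisible(x)
}

#' Absorbed dose of an arc plan on a density grid
#'
#' Sums, over all sampled gantry angles, weight x depth attenuation x
#' lateral transmission (Gaussian-penumbra-smoothed aperture). Linear in
#' the weights, non-negative, deterministic.
#'
#' @param plan An `rt_plan`.
#' @param density Numeric density array (water = 1), on the plan grid.
#' @param engine Optional [make_dose_engine()] cache for `density`.
#' @param angle_idx Angles to include (default all).
#' @param weights Per-angle weights overriding `plan$weights` (same length
#'   as `angle_idx`).
#' @param shift_mm Rigid aperture/isocenter shift as an (x, y, z) vector in
#'   mm (tracking); resolved into each angle's transverse frame.
#' @return A `dose_grid`: list with `values` (Gy array), `grid`,
#'   `provenance`.
#' @export
compute_arc_dose <- function(plan, density, engine = NULL, angle_idx = NULL,
                             weights = NULL, shift_mm = c(0, 0, 0)) {
  grid <- plan$grid
  if (!all(dim(density) == grid$shape)) {
    stop("geometry error: density does not match the plan grid")
  }
  if (is.null(engine)) engine <- make_dose_engine(density, grid, plan$beam)
  if (is.null(angle_idx)) angle_idx <- seq_along(plan$angles)
  if (is.null(weights)) weights <- plan$weights[angle_idx]
  if (all(vapply(plan$apertures[angle_idx], function(a) !any(a), logical(1)))) {
    stop("degenerate-plan error: all apertures are empty")
  }
  nax <- prod(grid$shape[1:2]); nz <- grid$shape[3]
  acc <- matrix(0, nax, nz)
  for (i in seq_along(angle_idx)) {
    ai <- angle_idx[i]
    if (weights[i] == 0) next
    fr <- bev_frame(plan$angles[ai])
    shift_uv <- c(shift_mm[1] * fr[1] + shift_mm[2] * fr[2], shift_mm[3])
    acc <- acc + weights[i] *
      angle_dose_matrix(engine, plan$tmaps[[ai]], plan$bev, plan$angles[ai], shift_uv)
  }
  dose_grid(array(plan$scale * acc, dim = grid$shape), grid,
            provenance = "3D")
}

#' Dose grid container
#'
#' @param values Non-negative Gy array.
#' @param grid `voxel_grid`.
#' @param provenance Free-text tag ("3D", "4D-accumulated", arm, ...).
#' @return Object of class `dose_grid`.
#' @export
dose_grid <- function(values, grid, provenance = "3D") {
  stopifnot(all(is.finite(values)), all(values >= 0))
  structure(list(values = values, grid = grid, provenance = provenance),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> [%s] max %.2f Gy, mean %.2f Gy\n",
              x$provenance, max(x$values), mean(x$values)))
  invisible(x)
}

#' Normalize a plan dose to the prescription
#'
#' Scales the dose so that D95 of the PTV equals the prescribed dose
#' (25 Gy): at least 95% of the PTV then receives the prescription. Also
#' reports the resulting global maximum and whether it respects the
#' 41.5 Gy ceiling (166% of prescription) — reported, not clipped.
#'
#' @param dose A `dose_grid`.
#' @param ptv_mask `rt_mask` of the PTV.
#' @param rx A [prescription_sbrt()].
#' @return List: `dose` (scaled `dose_grid`), `scale`, `d95`, `dmax`,
#'   `dmax_ok`.
#' @export
normalize_prescription <- function(dose, ptv_mask, rx = prescription_sbrt()) {
  dv <- dose$values[ptv_mask$voxels]
  if (length(dv) == 0) stop("empty-structure error: PTV mask is empty")
  # order statistic at rank ceiling(0.95 n): guarantees that at least 95%
  # of PTV voxels reach the prescription after scaling; the interpolated
  # D95 then equals the prescription within interpolation tolerance
  s <- sort(dv, decreasing = TRUE)
  d95 <- s[ceiling(rx$coverage_fraction * length(s))]
  if (d95 <= 0) stop("normalization error: zero dose in the PTV")
  scale <- rx$prescribed_dose_gy / d95
  out <- dose
  out$values <- dose$values * scale
  dmax <- max(out$values)
  list(dose = out, scale = scale, d95 = rx$prescribed_dose_gy,
       dmax = dmax, dmax_ok = dmax <= rx$max_dose_cap_gy)
}

#' Simultaneous-integrated-protection style aperture adjustment
#'
#' Iterative heuristic standing in for constrained inverse optimization:
#' while any hard planning objective fails (organ-at-risk limits, or the
#' near-maximum D0.1cc of a PTV/OAR overlap exceeding the 27.5 Gy window
#' ceiling) and fewer than `max_iter` iterations have run, the beam's-eye
#' projection of the overlap region (OAR expanded 2 mm, intersected with
#' the PTV) is subtracted from the apertures of the angles contributing
#' most to the excess, and the plan is renormalized to D95(PTV) = 25 Gy.
#' Deterministic: fixed angle ordering and iteration cap.
#'
#' `objectives_met` is TRUE when all hard constraints hold: every
#' organ-at-risk limit, PTV coverage at the prescription, and the overlap
#' window (D0.1cc of each overlap within 27.5 Gy, 95% of the overlap at
#' 25 Gy). The 27.5 Gy minimum aimed at in the non-overlapping PTV is
#' reported but does not gate the flag (it is an optimizer aspiration, not
#' attainable at a 25 Gy peripheral prescription).
#'
#' @param plan `rt_plan` (will be modified and returned).
#' @param dose Normalized `dose_grid` for `plan`.
#' @param sset `structure_set` providing PTV and OAR masks.
#' @param rx [prescription_sbrt()].
#' @param cset [constraint_set()].
#' @param engine Attenuation engine for the planning density.
#' @param max_iter Iteration cap (default 20).
#' @param carve_fraction Fraction of angles carved per iteration (default
#'   0.15, at least 8 angles).
#' @return List: `plan`, `dose` (renormalized), `objectives_met`,
#'   `report` (constraint tibble), `iterations`, `overlap_d01cc_history`
#'   (pre-normalization near-max of the overlap region per iteration).
#' @export
apply_sip_adjustment <- function(plan, dose, sset, rx = prescription_sbrt(),
                                 cset = constraint_set(), engine = NULL,
                                 max_iter = 20, carve_fraction = 0.15) {
  grid <- plan$grid
  if (is.null(engine)) engine <- make_dose_engine(sset$planning_density, grid, plan$beam)
  ptv <- sset$masks$ptv
  oar_names <- intersect(cset$structure, names(sset$masks))
  # overlap region: PTV intersected with each OAR expanded 2 mm
  overlaps <- list()
  for (nm in oar_names) {
    ov <- expand_margin(sset$masks[[nm]], 2)$voxels & ptv$voxels
    if (any(ov)) overlaps[[nm]] <- ov
  }
  hist_d01 <- numeric(0)
  it <- 0L
  nax <- prod(grid$shape[1:2]); nz <- grid$shape[3]
  # unit-scale total dose, updated incrementally as apertures are carved
  U <- matrix(dose$values / plan$scale, nax, nz)
  voxel_cc <- prod(grid$spacing) / 1000
  ov_all <- if (length(overlaps) > 0) Reduce(`|`, overlaps)
  repeat {
    report <- check_constraints(dose, sset, cset, rx)
    met <- attr(report, "objectives_met")
    if (met || it >= max_iter) break
    it <- it + 1L
    # hot voxels: union of overlap voxels above the window ceiling and
    # OAR voxels violating their limit
    hot <- array(FALSE, dim = grid$shape)
    for (nm in names(overlaps)) {
      hot <- hot | (overlaps[[nm]] & dose$values > rx$overlap_max_gy)
    }
    viol <- report[!report$pass & report$structure %in% oar_names, ]
    for (nm in unique(viol$structure)) {
      lim <- cset$limit_gy[cset$structure == nm]
      hot <- hot | (sset$masks[[nm]]$voxels & dose$values > lim)
    }
    if (!any(hot)) break   # failure not addressable by carving (e.g. coverage)
    carve_region <- array(FALSE, dim = grid$shape)
    for (nm in names(overlaps)) carve_region <- carve_region | overlaps[[nm]]
    for (nm in unique(viol$structure)) {
      carve_region <- carve_region |
        (expand_margin(sset$masks[[nm]], 2)$voxels & ptv$voxels)
    }
    if (!any(carve_region)) carve_region <- hot
    idx <- rank_contributing_angles(plan, engine, hot, grid)
    k <- max(8L, ceiling(carve_fraction * length(plan$angles)))
    sel <- idx[seq_len(min(k, length(idx)))]
    # carve the selected angles, updating only their dose contributions
    rmask <- rt_mask(carve_region, grid, "carve")
    for (ai in sel) {
      proj <- bev_aperture(rmask, plan$angles[ai], margin_mm = 2, bev = plan$bev)
      newap <- plan$apertures[[ai]] & !proj$aperture
      if (identical(newap, plan$apertures[[ai]])) next
      m_old <- angle_dose_matrix(engine, plan$tmaps[[ai]], plan$bev, plan$angles[ai])
      plan$apertures[[ai]] <- newap
      plan$tmaps[[ai]] <- transmission_map(newap, plan$bev$h, plan$bev$dv,
                                           plan$beam$sigma_mm)
      m_new <- angle_dose_matrix(engine, plan$tmaps[[ai]], plan$bev, plan$angles[ai])
      U <- U + plan$weights[ai] * (m_new - m_old)
    }
    U <- pmax(U, 0)
    if (!is.null(ov_all)) {
      # recorded at unit scale: the carving effect itself, before the
      # renormalization rescales the whole distribution
      ovd <- U[as.vector(ov_all)]
      hist_d01 <- c(hist_d01, if (length(ovd) * voxel_cc >= 0.1) {
        dose_at_absolute_volume(ovd, 0.1, voxel_cc = voxel_cc)
      } else {
        max(ovd)
      })
    }
    raw <- dose_grid(array(U, dim = grid$shape), grid, provenance = "3D")
    nrm <- normalize_prescription(raw, ptv, rx)
    dose <- nrm$dose
    plan$scale <- nrm$scale
  }
  list(plan = plan, dose = dose, objectives_met = attr(report, "objectives_met"),
       report = report, iterations = it, overlap_d01cc_history = hist_d01)
}

# Rank angles by their dose contribution to the hot voxel set (descending).
rank_contributing_angles <- function(plan, engine, hot, grid) {
  nax <- prod(grid$shape[1:2])
  hv <- which(hot)
  ax <- ((hv - 1) %% nax) + 1
  zi <- ((hv - 1) %/% nax) + 1
  contrib <- vapply(seq_along(plan$angles), function(ai) {
    att <- engine_atten(engine, plan$angles[ai])
    a <- if (is.matrix(att)) att[cbind(ax, zi)] else att[ax]
    fr <- bev_frame(plan$angles[ai])
    uq <- engine$xc[ax] * fr[1] + engine$yc[ax] * fr[2]
    vq <- engine$zc[zi]
    tv <- point_bilinear_uv(plan$tmaps[[ai]], plan$bev, uq, vq)
    plan$weights[ai] * mean(a * tv)
  }, numeric(1))
  order(contrib, decreasing = TRUE)
}

# Non-separable bilinear lookup (paired u, v query points).
point_bilinear_uv <- function(tmap, bev, uq, vq) {
  nu <- length(bev$ug); nv <- length(bev$vg)
  fu <- (uq - bev$ug[1]) / bev$h
  fv <- (vq - bev$vg[1]) / bev$dv
  ok <- fu >= 0 & fu <= nu - 1 & fv >= 0 & fv <= nv - 1
  i0 <- pmin(pmax(floor(fu), 0), nu - 2); wu <- fu - i0
  j0 <- pmin(pmax(floor(fv), 0), nv - 2); wv <- fv - j0
  tm <- tmap
  dim(tm) <- NULL
  id <- function(i, j) 1 + i + nu * j
  out <- tm[id(i0, j0)] * (1 - wu) * (1 - wv) + tm[id(i0 + 1, j0)] * wu * (1 - wv) +
    tm[id(i0, j0 + 1)] * (1 - wu) * wv + tm[id(i0 + 1, j0 + 1)] * wu * wv
  out[!ok] <- 0
  out
}

#' Plan the ITV (motion-envelope) arm
#'
#' Composition: build the ITV-arm structure set on the time-averaged
#' anatomy, conform a two-arc plan to the envelope PTV, normalize to the
#' prescription and run the overlap (SIP) adjustment.
#'
#' @param phantom A `four_d_phantom`.
#' @param margin_mm Target-to-PTV margin (default 5).
#' @param beam [beam_model()].
#' @param rx [prescription_sbrt()].
#' @param cset [constraint_set()].
#' @param aperture_margin_mm BEV aperture margin (default 0: the PTV surface
#'   sits mid-penumbra, reproducing the peripheral-prescription dose
#'   heterogeneity of a 60% isodose prescription).
#' @param sip Run the SIP adjustment (default TRUE).
#' @param sset Optional pre-built `structure_set` (must match the arm).
#' @return An `rt_treatment`: list with `arm`, `plan`, `dose` (normalized
#'   `dose_grid`), `structures`, `normalization`, `objectives_met`,
#'   `report`, `engine`.
#' @export
plan_itv <- function(phantom, margin_mm = 5, beam = beam_model(),
                     rx = prescription_sbrt(), cset = constraint_set(),
                     aperture_margin_mm = 0, sip = TRUE, sset = NULL) {
  plan_arm(phantom, "itv", margin_mm, beam, rx, cset, aperture_margin_mm, sip, sset)
}

#' Plan the tumor-tracking arm
#'
#' As [plan_itv()], but on the reference ("contouring") phase with the
#' reference GTV plus margin as PTV. With zero motion the two arms are
#' identical.
#'
#' @inheritParams plan_itv
#' @return An `rt_treatment`.
#' @export
plan_track <- function(phantom, margin_mm = 5, beam = beam_model(),
                       rx = prescription_sbrt(), cset = constraint_set(),
                       aperture_margin_mm = 0, sip = TRUE, sset = NULL) {
  plan_arm(phantom, "tracking", margin_mm, beam, rx, cset, aperture_margin_mm, sip, sset)
}

plan_arm <- function(phantom, arm, margin_mm, beam, rx, cset,
                     aperture_margin_mm, sip, sset = NULL) {
  if (is.null(sset)) sset <- build_structure_set(phantom, arm, margin_mm)
  stopifnot(sset$arm == arm)
  engine <- make_dose_engine(sset$planning_density, sset$grid, beam)
  plan <- make_arc_plan(sset$masks$ptv, beam = beam,
                        aperture_margin_mm = aperture_margin_mm)
  raw <- compute_arc_dose(plan, sset$planning_density, engine = engine)
  nrm <- normalize_prescription(raw, sset$masks$ptv, rx)
  plan$scale <- plan$scale * nrm$scale
  dose <- nrm$dose
  dose$provenance <- paste0("3D|", arm)
  if (sip) {
    adj <- apply_sip_adjustment(plan, dose, sset, rx, cset, engine = engine)
    plan <- adj$plan; dose <- adj$dose
    dose$provenance <- paste0("3D|", arm)
    objectives_met <- adj$objectives_met
    report <- adj$report
  } else {
    report <- check_constraints(dose, sset, cset, rx)
    objectives_met <- attr(report, "objectives_met")
  }
  structure(
    list(arm = arm, plan = plan, dose = dose, structures = sset,
         normalization = nrm[c("scale", "d95", "dmax", "dmax_ok")],
         objectives_met = objectives_met, report = report, engine = engine),
    class = "rt_treatment"
  )
}

#' @export
print.rt_treatment <- function(x, ...) {
  cat(sprintf(
    "<rt_treatment> arm '%s': PTV %.1f cm^3, Dmax %.1f Gy, objectives %s\n",
    x$arm, volume_cc(x$structures$masks$ptv), max(x$dose$values),
    if (isTRUE(x$objectives_met)) "met" else "NOT met"
  ))
  invisible(x)
}
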