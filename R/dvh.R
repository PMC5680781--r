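#' Cumulative dose-volume histogram
#'
#' Fraction of a structure's voxels receiving at least each dose level.
#' The curve is monotone non-increasing, starts at 1 at 0 Gy and reaches 0
#' beyond the maximum dose.
#'
#' @param dose A `dose_grid` (or numeric array).
#' @param mask `rt_mask` of the structure.
#' @param bin_width Dose bin width in Gy (default 0.05).
#' @return A tibble of class `dvh_curve` with columns `dose_gy` (bin edges)
#'   and `volume_fraction`, plus attributes `structure` and `bin_width`.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.05) {
  if (bin_width <= 0) stop("cumulative_dvh: bin_width must be positive")
  dv <- dose_values(dose)[mask$voxels]
  if (length(dv) == 0) stop("empty-structure error: mask has no voxels")
  edges <- seq(0, max(dv) + bin_width, by = bin_width)
  frac <- vapply(edges, function(e) mean(dv >= e), numeric(1))
  out <- tibble::tibble(dose_gy = edges, volume_fraction = frac)
  class(out) <- c("dvh_curve", class(out))
  attr(out, "structure") <- mask$label
  attr(out, "bin_width") <- bin_width
  out
}

dose_values <- function(dose) {
  if (inherits(dose, "dose_grid")) dose$values else dose
}

#' Dose received by at least x percent of a structure (DxX)
#'
#' Largest dose `d` such that at least `x_percent` of the structure
#' receives `>= d`, with linear interpolation between the descending-sorted
#' voxel doses at rank `x/100 * n` (rank-interpolated, not nearest-bin, so
#' 3-D and 4-D evaluations are directly comparable).
#'
#' @param dose_or_voxels A `dose_grid` (with `mask`) or a numeric vector of
#'   in-structure voxel doses.
#' @param x_percent Percentage in (0, 100].
#' @param mask Structure mask when a `dose_grid` is given.
#' @return Dose in Gy.
#' @export
dose_at_volume_percent <- function(dose_or_voxels, x_percent, mask = NULL) {
  if (x_percent <= 0 || x_percent > 100) {
    stop("domain error: x_percent must be in (0, 100]")
  }
  dv <- if (inherits(dose_or_voxels, "dose_grid")) {
    if (is.null(mask)) stop("a mask is required with a dose_grid")
    dose_or_voxels$values[mask$voxels]
  } else {
    as.numeric(dose_or_voxels)
  }
  if (length(dv) == 0) stop("empty-structure error: no voxel doses")
  s <- sort(dv, decreasing = TRUE)
  rank_interp(s, x_percent / 100 * length(s))
}

# dose at (possibly fractional) descending rank k, linear between
# neighbouring order statistics; k <= 1 returns the hottest voxel
rank_interp <- function(s, k) {
  n <- length(s)
  if (k <= 1) return(s[1])
  if (k >= n) return(s[n])
  lo <- floor(k)
  s[lo] + (s[lo + 1] - s[lo]) * (k - lo)
}

#' Dose to the hottest absolute volume (e.g. D0.1cc)
#'
#' Minimum dose among the hottest voxels whose cumulative volume first
#' reaches `cc`, with rank interpolation at the (generally fractional)
#' voxel index where the boundary falls.
#'
#' @param dose A `dose_grid` (with `mask`) or numeric vector of voxel doses
#'   (then supply `voxel_cc`).
#' @param cc Volume in cm^3, 0 < cc <= structure volume.
#' @param mask Structure mask when a `dose_grid` is given.
#' @param voxel_cc Volume of one voxel in cm^3 (required for a bare vector).
#' @return Dose in Gy.
#' @export
dose_at_absolute_volume <- function(dose, cc, mask = NULL, voxel_cc = NULL) {
  if (inherits(dose, "dose_grid")) {
    if (is.null(mask)) stop("a mask is required with a dose_grid")
    dv <- dose$values[mask$voxels]
    voxel_cc <- prod(dose$grid$spacing) / 1000
  } else {
    dv <- as.numeric(dose)
    if (is.null(voxel_cc)) stop("voxel_cc is required with a bare dose vector")
  }
  vol <- length(dv) * voxel_cc
  if (cc <= 0 || cc > vol) {
    stop(sprintf("domain error: cc must be in (0, %.3f]", vol))
  }
  s <- sort(dv, decreasing = TRUE)
  rank_interp(s, cc / voxel_cc)
}

#' Dose parameters of every structure for one evaluation mode
#'
#' In 3-D mode the target parameters are evaluated on the planning target
#' structure of the arm (the ITV for the motion-envelope arm, the reference
#' GTV for tracking) and the OARs on the planning structures. In 4-D mode
#' everything is evaluated on reference-phase structures, with the GTV as
#' target for both arms, so accumulated doses of the two arms are
#' compared on identical anatomy.
#'
#' @param dose `dose_grid` (a 3-D planning dose or a 4-D accumulated dose).
#' @param sset `structure_set` of the arm.
#' @param mode `"3D"` or `"4D"`.
#' @param phantom Required in 4-D mode: source of reference-phase masks.
#' @return Tibble of class `dose_metrics`: one row per structure with
#'   `Dmean`, `Dmin`, `Dmax`, `D2`, `D95`, `D98`, `D0.1cc` (Gy), plus
#'   `structure`, `mode`, `arm`, `volume_cc`.
#' @export
summarize_metrics <- function(dose, sset, mode = c("3D", "4D"), phantom = NULL) {
  mode <- match.arg(mode)
  masks <- if (mode == "3D") {
    m <- sset$masks
    m$gtv_ref <- NULL
    m$body <- NULL
    m$ptv <- NULL
    names(m)[names(m) == "target"] <- if (sset$arm == "itv") "itv" else "gtv"
    m
  } else {
    if (is.null(phantom)) stop("summarize_metrics: phantom required for 4D mode")
    ref <- phantom$phases[[phantom$reference_phase]]$masks
    ref$body <- NULL
    ref
  }
  rows <- lapply(names(masks), function(nm) {
    msk <- masks[[nm]]
    if (!any(msk$voxels)) return(NULL)
    dv <- dose_values(dose)[msk$voxels]
    voxel_cc <- prod(sset$grid$spacing) / 1000
    vol <- length(dv) * voxel_cc
    tibble::tibble(
      structure = nm, mode = mode, arm = sset$arm,
      volume_cc = vol,
      Dmean = mean(dv), Dmin = min(dv), Dmax = max(dv),
      D2 = dose_at_volume_percent(dv, 2),
      D95 = dose_at_volume_percent(dv, 95),
      D98 = dose_at_volume_percent(dv, 98),
      D0.1cc = if (vol >= 0.1) dose_at_absolute_volume(dv, 0.1, voxel_cc = voxel_cc) else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dose_metrics", class(out))
  out
}

#' Check planning objectives against a dose distribution
#'
#' Evaluates the organ-at-risk limits (strict inequalities), PTV coverage
#' (at least 95% of the PTV at the prescription dose) and, where the PTV
#' overlaps an OAR, the protection window (near-maximum D0.1cc of the
#' overlap at most 27.5 Gy and 95% of the overlap at the prescription).
#' The aspirational 27.5 Gy minimum in the non-overlapping PTV is reported
#' as a non-gating row (`gating = FALSE`).
#'
#' @param dose `dose_grid`.
#' @param sset `structure_set`.
#' @param cset [constraint_set()].
#' @param rx [prescription_sbrt()].
#' @return Tibble with columns `constraint`, `structure`, `value`, `limit`,
#'   `pass`, `gating`; attribute `objectives_met` is the conjunction of the
#'   gating rows.
#' @export
check_constraints <- function(dose, sset, cset = constraint_set(),
                              rx = prescription_sbrt()) {
  dvals <- dose_values(dose)
  rows <- list()
  for (r in seq_len(nrow(cset))) {
    nm <- cset$structure[r]
    if (!nm %in% names(sset$masks)) next
    dv <- dvals[sset$masks[[nm]]$voxels]
    if (length(dv) == 0) next
    val <- if (cset$metric[r] == "Dmax") max(dv) else mean(dv)
    rows[[length(rows) + 1]] <- tibble::tibble(
      constraint = paste0(nm, "_", cset$metric[r]), structure = nm,
      value = val, limit = cset$limit_gy[r],
      pass = val < cset$limit_gy[r], gating = TRUE
    )
  }
  ptv <- sset$masks$ptv
  ptv_dose <- dvals[ptv$voxels]
  cov <- mean(ptv_dose >= rx$prescribed_dose_gy)
  rows[[length(rows) + 1]] <- tibble::tibble(
    constraint = "ptv_coverage_V25", structure = "ptv", value = cov,
    limit = rx$coverage_fraction, pass = cov >= rx$coverage_fraction - 1e-9,
    gating = TRUE
  )
  rows[[length(rows) + 1]] <- tibble::tibble(
    constraint = "max_dose_cap", structure = "global", value = max(dvals),
    limit = rx$max_dose_cap_gy, pass = max(dvals) <= rx$max_dose_cap_gy,
    gating = TRUE
  )
  voxel_cc <- prod(sset$grid$spacing) / 1000
  ov_all <- array(FALSE, dim = sset$grid$shape)
  for (nm in intersect(cset$structure, names(sset$masks))) {
    ov <- sset$masks[[nm]]$voxels & ptv$voxels
    if (!any(ov)) next
    ov_all <- ov_all | ov
    ovd <- dvals[ov]
    d01 <- if (length(ovd) * voxel_cc >= 0.1) {
      dose_at_absolute_volume(ovd, 0.1, voxel_cc = voxel_cc)
    } else {
      max(ovd)
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      constraint = paste0("overlap_", nm, "_D0.1cc"), structure = nm,
      value = d01, limit = rx$overlap_max_gy, pass = d01 <= rx$overlap_max_gy,
      gating = TRUE
    )
    covov <- mean(ovd >= rx$overlap_min_gy)
    rows[[length(rows) + 1]] <- tibble::tibble(
      constraint = paste0("overlap_", nm, "_V25"), structure = nm,
      value = covov, limit = rx$coverage_fraction,
      pass = covov >= rx$coverage_fraction - 1e-9, gating = TRUE
    )
  }
  nonov <- ptv$voxels & !ov_all
  if (any(nonov)) {
    d98 <- dose_at_volume_percent(dvals[nonov], 98)
    rows[[length(rows) + 1]] <- tibble::tibble(
      constraint = "nonoverlap_ptv_aim_27.5", structure = "ptv",
      value = d98, limit = rx$nonoverlap_min_gy,
      pass = d98 >= rx$nonoverlap_min_gy, gating = FALSE
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "objectives_met") <- all(out$pass[out$gating])
  out
}
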