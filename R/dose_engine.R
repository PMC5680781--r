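#' Two-parameter photon beam model
#'
#' The declared surrogate for a clinical dose algorithm: a primary beam
#' attenuated exponentially with water-equivalent depth and blurred
#' laterally by a Gaussian penumbra. `mu` is the effective linear
#' attenuation coefficient (per mm; 0.004 approximates a 10 MV beam in
#' water), `sigma_mm` the penumbra standard deviation.
#'
#' @param mu Effective linear attenuation, mm^-1 (> 0).
#' @param sigma_mm Penumbra sigma, mm (> 0).
#' @param aperture_margin_mm Default margin added to beam's-eye-view
#'   apertures (mm).
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(mu = 0.004, sigma_mm = 3.0, aperture_margin_mm = 0) {
  if (mu <= 0 || sigma_mm <= 0) stop("beam_model: mu and sigma must be positive")
  structure(list(mu = mu, sigma_mm = sigma_mm,
                 aperture_margin_mm = aperture_margin_mm),
            class = "beam_model")
}

#' SBRT prescription (25 Gy in 5 fractions to the 60% isodose)
#'
#' The risk-adapted prescription simulated throughout: 5 x 5 Gy prescribed
#' to the 60% isodose surrounding the PTV (at least 95% of the PTV receives
#' 25 Gy), a reported maximum-dose ceiling of 41.5 Gy (166% of the
#' prescription), and a simultaneous-integrated-protection window: PTV
#' voxels overlapping an organ at risk may receive 25-27.5 Gy, while
#' non-overlapping PTV aims for at least 27.5 Gy.
#'
#' @return An object of class `prescription`.
#' @export
prescription_sbrt <- function() {
  p <- list(
    dose_per_fraction_gy = 5, n_fractions = 5, prescription_isodose = 0.60,
    prescribed_dose_gy = 25, max_dose_cap_gy = 41.5,
    overlap_min_gy = 25, overlap_max_gy = 27.5, nonoverlap_min_gy = 27.5,
    coverage_fraction = 0.95
  )
  stopifnot(p$prescribed_dose_gy == p$dose_per_fraction_gy * p$n_fractions,
            p$max_dose_cap_gy <= p$prescribed_dose_gy / p$prescription_isodose)
  structure(p, class = "prescription")
}

#' Organ-at-risk planning constraints
#'
#' Dmax < 25 Gy for the spinal cord, Dmax < 27.5 Gy for bowel, duodenum
#' and stomach, Dmean < 10 Gy for each kidney (strict inequalities).
#'
#' @return A tibble with columns `structure`, `metric`, `limit_gy`.
#' @export
constraint_set <- function() {
  tibble::tibble(
    structure = c("cord", "bowel", "duodenum", "stomach", "kidney_l", "kidney_r"),
    metric = c("Dmax", "Dmax", "Dmax", "Dmax", "Dmean", "Dmean"),
    limit_gy = c(25, 27.5, 27.5, 27.5, 10, 10)
  )
}

# ---- beam's-eye-view geometry -------------------------------------------
# Gantry rotates in the axial (x-y) plane. For angle theta (deg), the beam
# travels along b = (-sin, -cos); the transverse BEV frame uses the beam
# *line* (theta mod 180) so that opposed angles share one aperture:
# u = x*cos(theta') - y*sin(theta'), v = z.

bev_frame <- function(theta) {
  tp <- (theta %% 180) * pi / 180
  c(cos(tp), -sin(tp))
}

beam_dir <- function(theta) {
  t <- theta * pi / 180
  c(-sin(t), -cos(t))
}

make_bev_grid <- function(grid, pad_mm = 16) {
  h <- min(grid$spacing[1:2])
  corners <- expand.grid(x = range(axis_coords(grid, 1)), y = range(axis_coords(grid, 2)))
  R <- max(sqrt(corners$x^2 + corners$y^2)) + h
  ug <- seq(-R, R, by = h)
  zs <- axis_coords(grid, 3)
  vg <- seq(zs[1] - pad_mm, zs[length(zs)] + pad_mm, by = grid$spacing[3])
  list(ug = ug, vg = vg, h = h, dv = grid$spacing[3])
}

#' Beam's-eye-view aperture of a target
#'
#' Orthographic projection of the target along the beam line for a given
#' gantry angle (axial-plane rotation), optionally dilated by a margin.
#' A small morphological closing removes voxelisation pinholes. Opposed
#' gantry angles (theta and theta + 180) produce identical apertures
#' (parallel-beam symmetry).
#'
#' @param target_mask `rt_mask` of the target.
#' @param gantry_angle Gantry angle in degrees.
#' @param margin_mm Aperture margin (mm, >= 0).
#' @param bev Optional BEV grid from an existing plan (internal reuse).
#' @return An object of class `bev_aperture`: list with logical `aperture`
#'   (length(ug) x length(vg)), `ug`, `vg` and the angle.
#' @export
bev_aperture <- function(target_mask, gantry_angle, margin_mm = 0, bev = NULL) {
  if (!any(target_mask$voxels)) stop("empty-structure error: target mask is empty")
  grid <- target_mask$grid
  if (is.null(bev)) bev <- make_bev_grid(grid)
  fr <- bev_frame(gantry_angle)
  idx <- which(target_mask$voxels, arr.ind = TRUE)
  xs <- axis_coords(grid, 1)[idx[, 1]]
  ys <- axis_coords(grid, 2)[idx[, 2]]
  zs <- axis_coords(grid, 3)[idx[, 3]]
  u <- xs * fr[1] + ys * fr[2]
  iu <- round((u - bev$ug[1]) / bev$h) + 1
  iv <- round((zs - bev$vg[1]) / bev$dv) + 1
  ap <- matrix(FALSE, length(bev$ug), length(bev$vg))
  ap[cbind(iu, iv)] <- TRUE
  ap <- close_3x3(ap)
  if (margin_mm > 0) ap <- dilate_2d(ap, margin_mm, bev$h, bev$dv)
  structure(list(aperture = ap, ug = bev$ug, vg = bev$vg,
                 gantry_angle = gantry_angle, margin_mm = margin_mm),
            class = "bev_aperture")
}

# 3x3 binary closing (dilate then erode) to fill projection pinholes
close_3x3 <- function(m) {
  d <- shift_or_2d(m)
  !shift_or_2d(!d)
}

shift_or_2d <- function(m) {
  out <- m
  n1 <- nrow(m); n2 <- ncol(m)
  for (i in -1:1) for (j in -1:1) {
    if (i == 0 && j == 0) next
    xs <- max(1, 1 + i):min(n1, n1 + i)
    ys <- max(1, 1 + j):min(n2, n2 + j)
    out[xs, ys] <- out[xs, ys] | m[xs - i, ys - j]
  }
  out
}

dilate_2d <- function(m, margin_mm, h, dv) {
  allow <- min(h, dv) / 4
  reach <- margin_mm + allow
  ni <- ceiling(reach / h); nj <- ceiling(reach / dv)
  off <- expand.grid(i = -ni:ni, j = -nj:nj)
  off <- off[sqrt((off$i * h)^2 + (off$j * dv)^2) <= reach, , drop = FALSE]
  out <- matrix(FALSE, nrow(m), ncol(m))
  n1 <- nrow(m); n2 <- ncol(m)
  for (r in seq_len(nrow(off))) {
    i <- off$i[r]; j <- off$j[r]
    xs <- max(1, 1 + i):min(n1, n1 + i)
    ys <- max(1, 1 + j):min(n2, n2 + j)
    out[xs, ys] <- out[xs, ys] | m[xs - i, ys - j]
  }
  out
}

# Signed distance (mm, positive inside) from every BEV pixel to the
# aperture edge, brute force against boundary pixels (apertures are small).
signed_distance_2d <- function(ap, h, dv) {
  n1 <- nrow(ap); n2 <- ncol(ap)
  sd <- matrix(-Inf, n1, n2)
  if (!any(ap)) return(sd)
  inner_b <- ap & !shrink_4n(ap)      # aperture pixels touching outside
  outer_b <- !ap & shift_or_4n(ap)    # outside pixels touching aperture
  px <- rep((seq_len(n1) - 1) * h, times = n2)
  py <- rep((seq_len(n2) - 1) * dv, each = n1)
  d_to <- function(set) {
    bi <- which(set, arr.ind = TRUE)
    bx <- (bi[, 1] - 1) * h; by <- (bi[, 2] - 1) * dv
    best <- rep(Inf, length(px))
    for (q in seq_along(bx)) {
      best <- pmin(best, (px - bx[q])^2 + (py - by[q])^2)
    }
    sqrt(best)
  }
  half <- min(h, dv) / 2
  if (any(outer_b)) {
    din <- d_to(outer_b)              # distance to nearest outside pixel
    dout <- d_to(inner_b)             # distance to nearest inside pixel
    sdv <- ifelse(ap, din - half, -(dout - half))
  } else {
    sdv <- ifelse(ap, Inf, -Inf)      # aperture fills the grid
  }
  matrix(sdv, n1, n2)
}

shrink_4n <- function(m) {
  out <- m
  n1 <- nrow(m); n2 <- ncol(m)
  pad <- function(i, j) {
    mm <- matrix(FALSE, n1, n2)
    xs <- max(1, 1 + i):min(n1, n1 + i)
    ys <- max(1, 1 + j):min(n2, n2 + j)
    mm[xs, ys] <- m[xs - i, ys - j]
    mm
  }
  out & pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
}

shift_or_4n <- function(m) {
  out <- m
  n1 <- nrow(m); n2 <- ncol(m)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    xs <- max(1, 1 + d[1]):min(n1, n1 + d[1])
    ys <- max(1, 1 + d[2]):min(n2, n2 + d[2])
    out[xs, ys] <- out[xs, ys] | m[xs - d[1], ys - d[2]]
  }
  out
}

# Transmission map: aperture indicator convolved with the Gaussian
# penumbra, realised as a normal CDF of the signed edge distance.
transmission_map <- function(ap, h, dv, sigma_mm) {
  sd <- signed_distance_2d(ap, h, dv)
  stats::pnorm(sd / sigma_mm)
}

# ---- attenuation engine --------------------------------------------------
# Radiological depth is water-equivalent path length through the density
# grid, integrated along the (axial) beam direction. Because the gantry
# rotates in the axial plane, rays never cross axial slices: depth is a
# per-slice 2-D computation. When the density is identical in every slice
# (z-extruded body, no tumor contrast) a single slice serves all of them.

#' Create a cached attenuation engine for a density grid
#'
#' Precomputes per-gantry-angle attenuation factors
#' `exp(-mu * radiological_depth)` lazily and caches them, so that plans,
#' iterative aperture adjustment and 4-D accumulation reuse the same
#' depth computations.
#'
#' @param density Numeric 3-D array (water = 1, air = 0).
#' @param grid The `voxel_grid` of `density`.
#' @param beam A [beam_model()].
#' @return An environment of class `dose_engine`.
#' @export
make_dose_engine <- function(density, grid, beam = beam_model()) {
  e <- new.env(parent = emptyenv())
  e$grid <- grid
  e$beam <- beam
  e$density <- density
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2)
  e$xc <- rep(xs, times = ny)      # axial voxel x, length nx*ny
  e$yc <- rep(ys, each = nx)
  e$zc <- axis_coords(grid, 3)
  # z-invariance check
  s1 <- density[, , 1]
  e$zinv <- all(vapply(seq_len(nz), function(k) identical(density[, , k], s1) ||
                         max(abs(density[, , k] - s1)) == 0, logical(1)))
  h <- min(grid$spacing[1:2])
  R <- max(sqrt(e$xc^2 + e$yc^2)) + h
  e$depth_s <- seq(-R, R, by = h)
  e$h <- h
  e$cache <- new.env(parent = emptyenv())
  class(e) <- c("dose_engine", "environment")
  e
}

# 2-D radiological depth of all axial voxels for one slice and angle.
slice_depth <- function(e, slice, theta) {
  b <- beam_dir(theta)
  a <- c(-b[2], b[1])                       # transverse axis of depth frame
  s <- e$depth_s; h <- e$h
  nu <- length(s)
  grid <- e$grid
  # density sampled on the beam-aligned lattice (nearest neighbour)
  X <- outer(s * a[1], s * b[1], "+")
  Y <- outer(s * a[2], s * b[2], "+")
  ix <- round((X - grid$origin[1]) / grid$spacing[1]) + 1
  iy <- round((Y - grid$origin[2]) / grid$spacing[2]) + 1
  ok <- ix >= 1 & ix <= grid$shape[1] & iy >= 1 & iy <= grid$shape[2]
  dens <- matrix(0, nu, nu)
  dens[ok] <- slice[cbind(ix[ok], iy[ok])]
  # cumulative water-equivalent path along the beam axis (columns = w)
  cum <- t(apply(dens, 1, cumsum))
  depth_uw <- (cum - 0.5 * dens) * h
  # pull depth back to the axial voxel centres (bilinear in (u, w))
  uq <- e$xc * a[1] + e$yc * a[2]
  wq <- e$xc * b[1] + e$yc * b[2]
  fu <- (uq - s[1]) / h; fw <- (wq - s[1]) / h
  i0 <- pmin(pmax(floor(fu), 0), nu - 2); wu <- fu - i0
  j0 <- pmin(pmax(floor(fw), 0), nu - 2); ww <- fw - j0
  d <- depth_uw
  dim(d) <- NULL
  id <- function(i, j) 1 + i + nu * j
  d[id(i0, j0)] * (1 - wu) * (1 - ww) + d[id(i0 + 1, j0)] * wu * (1 - ww) +
    d[id(i0, j0 + 1)] * (1 - wu) * ww + d[id(i0 + 1, j0 + 1)] * wu * ww
}

# Attenuation factors for one gantry angle: matrix (nx*ny) x nz (or an
# (nx*ny)-vector when density is z-invariant), zero outside the body.
engine_atten <- function(e, theta) {
  key <- sprintf("a%.4f", theta %% 360)
  got <- get0(key, envir = e$cache)
  if (!is.null(got)) return(got)
  mu <- e$beam$mu
  if (e$zinv) {
    slice <- e$density[, , 1]
    depth <- slice_depth(e, slice, theta)
    att <- exp(-mu * depth)
    att[as.vector(slice) <= 0] <- 0
  } else {
    nz <- e$grid$shape[3]
    att <- matrix(0, length(e$xc), nz)
    for (k in seq_len(nz)) {
      slice <- e$density[, , k]
      if (!any(slice > 0)) next
      depth <- slice_depth(e, slice, theta)
      col <- exp(-mu * depth)
      col[as.vector(slice) <= 0] <- 0
      att[, k] <- col
    }
  }
  assign(key, att, envir = e$cache)
  att
}

# Dose matrix ((nx*ny) x nz) for one angle: attenuation times the
# transmission map sampled at the (possibly shifted) BEV coordinates.
angle_dose_matrix <- function(e, tmap, bev, theta, shift_uv = c(0, 0)) {
  fr <- bev_frame(theta)
  uq <- e$xc * fr[1] + e$yc * fr[2] - shift_uv[1]
  vq <- e$zc - shift_uv[2]
  M <- bilinear_uv(tmap, bev, uq, vq)
  att <- engine_atten(e, theta)
  if (is.matrix(att)) M * att else M * as.vector(att)
}

# Separable bilinear lookup of a BEV map at axial u (length nx*ny) and
# slice v (length nz) coordinates; outside the map -> 0.
bilinear_uv <- function(tmap, bev, uq, vq) {
  nu <- length(bev$ug); nv <- length(bev$vg)
  fu <- (uq - bev$ug[1]) / bev$h
  fv <- (vq - bev$vg[1]) / bev$dv
  oku <- fu >= 0 & fu <= nu - 1
  okv <- fv >= 0 & fv <= nv - 1
  i0 <- pmin(pmax(floor(fu), 0), nu - 2); wu <- fu - i0
  j0 <- pmin(pmax(floor(fv), 0), nv - 2); wv <- fv - j0
  i0 <- i0 + 1; j0 <- j0 + 1
  A00 <- tmap[i0, j0]; A10 <- tmap[i0 + 1, j0]
  A01 <- tmap[i0, j0 + 1]; A11 <- tmap[i0 + 1, j0 + 1]
  wu1 <- 1 - wu
  Mv0 <- A00 * wu1 + A10 * wu
  Mv1 <- A01 * wu1 + A11 * wu
  nax <- length(uq)
  W <- rep(wv, each = nax)
  M <- Mv0 * (1 - W) + Mv1 * W
  M[!oku, ] <- 0
  M[, !okv] <- 0
  M
}
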