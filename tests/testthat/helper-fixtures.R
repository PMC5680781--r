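# Shared fixtures and independent oracles. Unit tests run on reduced grids
# (24^3-48^3) with proportionally scaled organs; acceptance tests use the
# full 64^3 study geometry.

# Organ set scaled to fit a smaller grid. `scale` multiplies all organ
# positions/sizes of the default anatomy; the duodenal gap is settable
# separately because several tests need overlap-free geometry.
scaled_organs <- function(scale = 0.5, duodenum_gap_mm = 8 * scale) {
  org <- default_organs(
    gtv_semi_axes_mm = c(14, 12, 14) * scale,
    duodenum_gap_mm = duodenum_gap_mm,
    duodenum_radius_mm = 6 * scale,
    body_semi_axes_mm = c(58, 52) * scale
  )
  for (nm in setdiff(names(org), c("body", "gtv", "duodenum"))) {
    org[[nm]]$center <- org[[nm]]$center * scale
    if (!is.null(org[[nm]]$semi_axes)) org[[nm]]$semi_axes <- org[[nm]]$semi_axes * scale
    if (!is.null(org[[nm]]$radius)) org[[nm]]$radius <- org[[nm]]$radius * scale
    if (!is.null(org[[nm]]$z_range)) org[[nm]]$z_range <- org[[nm]]$z_range * scale
  }
  org$duodenum$z_range <- c(-30, 30) * scale
  org
}

small_phantom_config <- function(amp = c(ap = 2, si = 5, lr = 1),
                                 n = 32, scale = 0.45, ...) {
  phantom_config(
    grid_shape = rep(n, 3), spacing_mm = 2,
    motion_amplitude_mm = amp,
    organs = scaled_organs(scale), ...
  )
}

# sphere mask centred in a fresh grid
sphere_mask <- function(radius_mm, n = 24, spacing = 2, center = c(0, 0, 0)) {
  g <- voxel_grid(rep(n, 3), spacing)
  vox <- ellipsoid_voxels(g, center, rep(radius_mm, 3))
  rt_mask(vox, g, "sphere")
}

# ---- independent oracles -------------------------------------------------

# DxX by explicit descending sort and rank interpolation (the stated rule,
# coded independently of the package internals)
oracle_dxx <- function(doses, x_percent) {
  s <- sort(doses, decreasing = TRUE)
  n <- length(s)
  k <- x_percent / 100 * n
  if (k <= 1) return(s[1])
  if (k >= n) return(s[n])
  lo <- floor(k)
  s[lo] * (1 - (k - lo)) + s[lo + 1] * (k - lo)
}

oracle_dcc <- function(doses, cc, voxel_cc) {
  s <- sort(doses, decreasing = TRUE)
  k <- cc / voxel_cc
  n <- length(s)
  if (k <= 1) return(s[1])
  if (k >= n) return(s[n])
  lo <- floor(k)
  s[lo] * (1 - (k - lo)) + s[lo + 1] * (k - lo)
}

# Exact Wilcoxon signed-rank two-sided p by complete enumeration of all
# 2^n sign vectors (midranks; zero differences removed by the caller)
oracle_wilcoxon_enum <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  lower <- mean(vs <= v_obs + 1e-12)
  upper <- mean(vs >= v_obs - 1e-12)
  min(1, 2 * min(lower, upper))
}
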