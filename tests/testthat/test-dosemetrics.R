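test_that("cumulative DVH has the step structure of the voxel doses", {
  g <- voxel_grid(c(10, 10, 10), 2)
  m <- rt_mask(array(TRUE, c(10, 10, 10)), g, "all")

  uni <- dose_grid(array(12, c(10, 10, 10)), g)
  curve <- cumulative_dvh(uni, m)
  expect_equal(curve$volume_fraction[curve$dose_gy <= 12], rep(1, sum(curve$dose_gy <= 12)))
  expect_equal(curve$volume_fraction[curve$dose_gy > 12], rep(0, sum(curve$dose_gy > 12)))

  half <- array(10, c(10, 10, 10)); half[1:5, , ] <- 30
  hd <- dose_grid(half, g)
  curve <- cumulative_dvh(hd, m)
  mid <- curve$dose_gy > 10 & curve$dose_gy <= 30
  expect_equal(curve$volume_fraction[mid], rep(0.5, sum(mid)))

  # monotone non-increasing, endpoints 1 -> 0
  expect_true(all(diff(curve$volume_fraction) <= 0))
  expect_equal(curve$volume_fraction[1], 1)
  expect_equal(curve$volume_fraction[nrow(curve)], 0)
  expect_error(cumulative_dvh(uni, rt_mask(array(FALSE, c(10, 10, 10)), g)),
               "empty-structure")
  expect_error(cumulative_dvh(uni, m, bin_width = 0), "bin_width")
})

test_that("DxX matches the descending-sort oracle and its examples", {
  expect_equal(dose_at_volume_percent(rep(7, 50), 95), 7)
  # 100 voxels with doses 1..100: D95 between 5 and 6; the rank rule fixes it
  d <- 1:100
  expect_equal(dose_at_volume_percent(d, 95), oracle_dxx(d, 95))
  expect_gte(dose_at_volume_percent(d, 95), 5)
  expect_lte(dose_at_volume_percent(d, 95), 6)
  expect_error(dose_at_volume_percent(d, 0), "domain error")
  expect_error(dose_at_volume_percent(d, 101), "domain error")

  set.seed(11)
  for (i in 1:100) {
    dv <- stats::runif(sample(20:400, 1), 0, 45)
    for (x in c(2, 95, 98, sample(1:99, 1))) {
      expect_equal(dose_at_volume_percent(dv, x), oracle_dxx(dv, x), tolerance = 1e-12)
    }
    expect_lte(dose_at_volume_percent(dv, 98), dose_at_volume_percent(dv, 95))
    expect_lte(dose_at_volume_percent(dv, 95), dose_at_volume_percent(dv, 2))
  }
})

test_that("dose to an absolute hot volume follows the hottest-voxel rule", {
  vox_cc <- 0.008                     # 2 mm voxels
  expect_equal(dose_at_absolute_volume(rep(14, 100), 0.1, voxel_cc = vox_cc), 14)
  # one 8 mm^3 voxel at 40 Gy, the rest at 10 Gy, cc = 0.1: the hottest
  # 0.1 cc is 0.008 cc at 40 plus 0.092 cc at 10 -> its minimum dose is 10
  dv <- c(40, rep(10, 199))
  expect_equal(dose_at_absolute_volume(dv, 0.1, voxel_cc = vox_cc), 10)
  expect_equal(dose_at_absolute_volume(dv, 0.1, voxel_cc = vox_cc),
               oracle_dcc(dv, 0.1, vox_cc))
  # monotone: larger volume, smaller or equal dose
  set.seed(3)
  dv <- stats::runif(300, 0, 40)
  ccs <- c(0.01, 0.05, 0.1, 0.5, 1)
  vals <- vapply(ccs, function(cc) dose_at_absolute_volume(dv, cc, voxel_cc = vox_cc),
                 numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_error(dose_at_absolute_volume(dv, 10, voxel_cc = vox_cc), "domain error")
})

test_that("structure metrics match brute-force voxel statistics and scale linearly", {
  set.seed(21)
  g <- voxel_grid(c(10, 10, 10), 2)
  vals <- array(stats::runif(1000, 0, 40), c(10, 10, 10))
  msk <- rt_mask(array(stats::runif(1000) < 0.4, c(10, 10, 10)), g, "roi")
  sset <- structure(
    list(arm = "tracking", margin_mm = 5, grid = g,
         masks = list(target = msk), planning_density = NULL),
    class = "structure_set"
  )
  m <- summarize_metrics(dose_grid(vals, g), sset, "3D")
  dv <- vals[msk$voxels]
  expect_equal(m$Dmean, mean(dv))
  expect_equal(m$Dmin, min(dv))
  expect_equal(m$Dmax, max(dv))
  expect_equal(m$D2, oracle_dxx(dv, 2))
  expect_equal(m$D95, oracle_dxx(dv, 95))
  expect_equal(m$D98, oracle_dxx(dv, 98))
  expect_equal(m[["D0.1cc"]], oracle_dcc(dv, 0.1, 0.008))

  # uniform dose: all seven parameters coincide
  mu <- summarize_metrics(dose_grid(array(9, g$shape), g), sset, "3D")
  for (p in c("Dmean", "Dmin", "Dmax", "D2", "D95", "D98", "D0.1cc")) {
    expect_equal(mu[[p]], 9, tolerance = 1e-12)
  }
  # scale equivariance of the full table
  k <- 1.7
  mk <- summarize_metrics(dose_grid(k * vals, g), sset, "3D")
  for (p in c("Dmean", "Dmin", "Dmax", "D2", "D95", "D98", "D0.1cc")) {
    expect_equal(mk[[p]], k * m[[p]], tolerance = 1e-12)
  }
})

test_that("evaluation modes pick the correct target structures", {
  ph <- make_phantom(small_phantom_config(amp = c(ap = 2, si = 6, lr = 1), n = 32))
  ssi <- build_structure_set(ph, "itv")
  sst <- build_structure_set(ph, "tracking")
  d <- dose_grid(array(10, ssi$grid$shape), ssi$grid)
  m3i <- summarize_metrics(d, ssi, "3D")
  m3t <- summarize_metrics(d, sst, "3D")
  expect_true("itv" %in% m3i$structure)
  expect_true("gtv" %in% m3t$structure)
  m4 <- summarize_metrics(d, ssi, "4D", phantom = ph)
  expect_true("gtv" %in% m4$structure)
  expect_error(summarize_metrics(d, ssi, "4D"), "phantom")
})

test_that("constraint checks use strict limits and conjunction semantics", {
  ph <- make_phantom(small_phantom_config(amp = c(ap = 0, si = 0, lr = 0), n = 32))
  ss <- build_structure_set(ph, "tracking")
  zero <- dose_grid(array(0, ss$grid$shape), ss$grid)
  rep0 <- check_constraints(zero, ss)
  oar_rows <- rep0[grepl("_(Dmax|Dmean)$", rep0$constraint) &
                     !grepl("^overlap_", rep0$constraint), ]
  expect_true(all(oar_rows$pass))
  expect_false(rep0$pass[rep0$constraint == "ptv_coverage_V25"])
  expect_false(attr(rep0, "objectives_met"))

  # cord Dmax exactly at the 25 Gy limit fails the strict inequality
  at_limit <- array(0, ss$grid$shape)
  at_limit[ss$masks$cord$voxels] <- 25
  at_limit[ss$masks$ptv$voxels] <- 26
  repl <- check_constraints(dose_grid(at_limit, ss$grid), ss)
  expect_false(repl$pass[repl$constraint == "cord_Dmax"])
  expect_equal(attr(repl, "objectives_met"), all(repl$pass[repl$gating]))
})

test_that("metrics are homogeneous of degree one in the dose", {
  set.seed(5)
  dv <- stats::runif(500, 0, 30)
  k <- 2.3
  for (x in c(2, 95, 98)) {
    expect_equal(dose_at_volume_percent(k * dv, x), k * dose_at_volume_percent(dv, x),
                 tolerance = 1e-12)
  }
  expect_equal(dose_at_absolute_volume(k * dv, 0.3, voxel_cc = 0.008),
               k * dose_at_absolute_volume(dv, 0.3, voxel_cc = 0.008),
               tolerance = 1e-12)
})
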