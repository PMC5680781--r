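arc1 <- function() default_arcs()[1, ]

test_that("arc segmentation partitions the arc with exact MU shares", {
  # arc duration exactly one breathing period, 10 phases: 10 x 36 deg
  segs <- segment_arc_by_phase(arc1(), gantry_speed_deg_s = 90,
                               breathing_period_s = 4, n_phases = 10)
  expect_equal(nrow(segs), 10)
  expect_equal(abs(segs$angle_to - segs$angle_from), rep(36, 10))
  expect_equal(segs$share, rep(0.1, 10))
  expect_equal(segs$phase, 1:10)
  expect_equal(sum(segs$share), 1)

  # k whole periods: every phase accumulates exactly 1/n of the arc MU
  for (k in c(2, 5)) {
    segs <- segment_arc_by_phase(arc1(), gantry_speed_deg_s = 360 / (k * 4),
                                 breathing_period_s = 4, n_phases = 10)
    by_phase <- tapply(segs$share, segs$phase, sum)
    expect_equal(as.numeric(by_phase), rep(1 / 10, 10), tolerance = 1e-12)
    expect_equal(sum(segs$share), 1, tolerance = 1e-12)
  }

  # non-commensurate speed: shares still partition to 1
  segs <- segment_arc_by_phase(arc1(), gantry_speed_deg_s = 3.7,
                               breathing_period_s = 3.9, n_phases = 10,
                               start_phase = 4)
  expect_equal(sum(segs$share), 1, tolerance = 1e-12)
  expect_true(all(segs$phase %in% 1:10))

  expect_error(segment_arc_by_phase(arc1(), 0, 4, 10), "invalid-config")
  expect_error(segment_arc_by_phase(arc1(), 3, -1, 10), "invalid-config")
})

test_that("per-phase MU shares approach 1/n for long deliveries", {
  ph <- make_phantom(small_phantom_config(n = 24))
  tt <- plan_track(ph, sip = FALSE)
  # 50 breathing periods per arc (plus an offset so it is not commensurate)
  speed <- 360 / (50.37 * 4)
  W <- trackdose:::angle_phase_weights(tt$plan, speed, 4, 10, 1)
  expect_equal(sum(W), 1, tolerance = 1e-12)           # MU conservation
  expect_true(all(abs(colSums(W) - 0.1) < 0.01 * 0.1)) # within 1% of 1/n
})

test_that("dose warping is exact for zero fields and closed-form for shifts", {
  g <- voxel_grid(rep(24, 3), 2)
  zs <- axis_coords(g, 3)
  ramp <- array(rep(30 + 0.5 * zs, each = 24 * 24), dim = g$shape)  # a*z + b
  dg <- dose_grid(ramp, g)
  f0 <- trackdose:::displacement_field(g, 1, c(0, 0, 0))
  expect_identical(warp_dose_to_reference(dg, f0)$values, dg$values)

  shift <- c(0, 0, 3.1)
  fs <- trackdose:::displacement_field(g, 2, shift)
  w <- warp_dose_to_reference(dg, fs)
  interior <- abs(rep(zs, each = 24 * 24) + shift[3]) < max(zs) - 2
  expect_equal(w$values[interior],
               (ramp + 0.5 * shift[3])[interior], tolerance = 1e-6)
  expect_true(all(w$values >= 0))

  g2 <- voxel_grid(rep(20, 3), 2)
  f_bad <- trackdose:::displacement_field(g2, 2, shift)
  expect_error(warp_dose_to_reference(dg, f_bad), "geometry error")
})

test_that("phase sub-doses reproduce angular slices and rigid shifts", {
  ph <- make_phantom(small_phantom_config(amp = c(ap = 0, si = 6, lr = 0), n = 32))
  tt <- plan_track(ph, sip = FALSE)
  ref <- ph$reference_phase
  segs <- segment_arc_by_phase(arc1(), gantry_speed_deg_s = 90,
                               breathing_period_s = 4, n_phases = 10,
                               start_phase = ref)
  seg_ref <- segs[1, ]                       # delivered during the reference phase
  expect_equal(seg_ref$phase, ref)
  sub_itv <- phase_subdose(tt, seg_ref, ph, "itv")
  sub_trk <- phase_subdose(tt, seg_ref, ph, "tracking")
  # on the reference phase both modes equal the same angular slice of the
  # static dose: the 36 deg segment covers 7 full 5-deg bins plus 0.2 of
  # the eighth
  idx <- which(tt$plan$arc_id == 1)[1:8]
  slice <- compute_arc_dose(tt$plan, ph$phases[[ref]]$density,
                            angle_idx = idx,
                            weights = tt$plan$weights[idx] * c(rep(1, 7), 0.2))
  expect_equal(sub_itv$values, slice$values, tolerance = 1e-9)
  expect_equal(sub_trk$values, slice$values, tolerance = 1e-9)

  # tracking sub-dose on a displaced phase equals the reference sub-dose
  # rigidly translated by the phase displacement
  k <- which.max(ph$trace)
  seg_k <- segs[segs$phase == k, ][1, ]
  sub_k <- phase_subdose(tt, seg_k, ph, "tracking")
  seg_same_angles <- seg_k; seg_same_angles$phase <- ref
  sub_ref <- phase_subdose(tt, seg_same_angles, ph, "tracking")
  d <- trackdose:::phase_shift_3d(ph, k)
  pts <- grid_coords(tt$plan$grid)
  translated <- trilinear_sample(sub_ref$values, tt$plan$grid,
                                 sweep(pts, 2, d), outside = NA)
  ok <- !is.na(translated)
  expect_gt(stats::cor(translated[ok], as.vector(sub_k$values)[ok]), 0.999)
  expect_lt(max(abs(translated[ok] - as.vector(sub_k$values)[ok])), 0.02 * max(sub_k$values))

  # a zero-extent segment delivers no dose
  seg0 <- seg_ref; seg0$angle_to <- seg0$angle_from
  expect_true(all(phase_subdose(tt, seg0, ph, "itv")$values == 0))
  expect_error(phase_subdose(tt, seg_ref, ph, "nope"))
})

test_that("zero-motion 4-D accumulation equals the static dose in both arms", {
  ph0 <- make_phantom(small_phantom_config(amp = c(ap = 0, si = 0, lr = 0), n = 32))
  for (planner in list(plan_itv, plan_track)) {
    tr <- planner(ph0, sip = FALSE)
    acc <- accumulate_4d(tr, ph0)
    expect_lt(max(abs(acc$dose$values - tr$dose$values)), 1e-6)
    expect_equal(sum(acc$phase_weights), 1, tolerance = 1e-12)
  }
})

test_that("perfect tracking under rigid motion preserves the GTV dose", {
  ph <- make_phantom(small_phantom_config(amp = c(ap = 2, si = 8, lr = 1), n = 32))
  tt <- plan_track(ph, sip = FALSE)
  acc <- accumulate_4d(tt, ph)
  gtv <- ph$phases[[ph$reference_phase]]$masks$gtv
  d3 <- mean(tt$dose$values[gtv$voxels])
  d4 <- mean(acc$dose$values[gtv$voxels])
  expect_lt(abs(d4 - d3), 0.02 * prescription_sbrt()$prescribed_dose_gy)
})

test_that("tracking is at least as motion-robust as the envelope arm for the GTV", {
  ph <- make_phantom(small_phantom_config(amp = c(ap = 2, si = 8, lr = 1), n = 32))
  ti <- plan_itv(ph, sip = FALSE)
  tt <- plan_track(ph, sip = FALSE)
  ai <- accumulate_4d(ti, ph)
  at <- accumulate_4d(tt, ph)
  gtv <- ph$phases[[ph$reference_phase]]$masks$gtv
  d95_itv4 <- dose_at_volume_percent(ai$dose, 95, gtv)
  d95_trk4 <- dose_at_volume_percent(at$dose, 95, gtv)
  d95_itv3 <- dose_at_volume_percent(ti$dose, 95, gtv)
  d95_trk3 <- dose_at_volume_percent(tt$dose, 95, gtv)
  # bounds: breathing motion cannot improve on the static envelope plan
  expect_gte(d95_itv4, 0)
  expect_lte(d95_itv4, d95_itv3 + 0.05)
  # motion robustness: accumulating over the cycle degrades the tracking
  # arm's GTV coverage no more than the envelope arm's
  expect_lte(d95_trk3 - d95_trk4, (d95_itv3 - d95_itv4) + 0.1)
})
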