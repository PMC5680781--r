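test_that("the bundled cohort loads, validates and derives consistently", {
  rec <- load_table1()
  expect_equal(nrow(rec), 12)
  p7 <- rec[rec$patient == 7, ]
  expect_equal(c(p7$ptv_itv_cc, p7$ptv_track_cc, p7$ap_mm, p7$si_mm, p7$lr_mm),
               c(83.0, 70.6, 1.0, 1.6, 0.8))
  expect_equal(p7$motion3d_mm, 2.1)
  # recomputed 3-D motion agrees with the printed column within the
  # rounding of the 1-d.p. per-axis inputs
  expect_true(all(abs(rec$motion3d_recomputed_mm - rec$motion3d_mm) <= 0.15))
  expect_equal(rec$reduction_pct,
               -100 * (rec$ptv_itv_cc - rec$ptv_track_cc) / rec$ptv_itv_cc)
})

test_that("cohort summary reproduces the printed medians, means and reduction", {
  sm <- summarize_cohort(load_table1())
  g <- function(col, stat) sm$columns[[stat]][sm$columns$column == col]
  expect_lt(abs(g("ptv_itv_cc", "median") - 131.3), 0.1)
  expect_lt(abs(g("ptv_itv_cc", "mean") - 142.8), 0.1)
  expect_lt(abs(g("ptv_itv_cc", "sd") - 71.2), 0.1)
  expect_lt(abs(g("ptv_track_cc", "median") - 109.0), 0.1)
  expect_lt(abs(g("ptv_track_cc", "mean") - 121.7), 0.1)
  expect_lt(abs(sm$reduction$mean_pct - 16.8), 0.1)
  expect_lt(abs(sm$reduction$sd_pct - 8.4), 0.1)
  expect_lt(abs(sm$reduction$min_pct - 4.7), 0.1)
  expect_lt(abs(sm$reduction$max_pct - 39.2), 0.1)
  # median always inside the interquartile interval
  expect_true(all(sm$columns$p25 <= sm$columns$median))
  expect_true(all(sm$columns$median <= sm$columns$p75))
  expect_error(summarize_cohort(load_table1()[0, ]), "empty")
})

test_that("exact Wilcoxon signed-rank matches complete sign enumeration", {
  rec <- load_table1()
  # all 12 differences share one sign and are untied: p = 2 / 2^12
  w <- wilcoxon_signed_rank(rec$ptv_itv_cc, rec$ptv_track_cc)
  expect_equal(w$p.value, 2 / 4096)
  expect_equal(unname(w$statistic), 12 * 13 / 2)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "undefined-test")

  set.seed(99)
  for (trial in 1:200) {
    n <- sample(3:12, 1)
    a <- round(stats::runif(n, 0, 10), sample(0:1, 1))  # induces occasional ties
    b <- round(stats::runif(n, 0, 10), 1)
    if (all(a == b)) next
    expect_equal(wilcoxon_signed_rank(a, b)$p.value,
                 oracle_wilcoxon_enum(a, b), tolerance = 1e-12)
  }
  # cross-check against the reference implementation where it is exact
  set.seed(7)
  for (trial in 1:20) {
    a <- stats::rnorm(10); b <- stats::rnorm(10)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(wilcoxon_signed_rank(a, b)$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Spearman correlation uses midranks with the t-approximation p-value", {
  rec <- load_table1()
  sp <- spearman_rho(rec$motion3d_mm, rec$reduction_pct)
  expect_lt(abs(unname(sp$statistic["rho"]) - (-0.46)), 0.01)
  expect_lt(abs(sp$p.value - 0.131), 0.01)

  expect_equal(unname(spearman_rho(1:8, (1:8)^3)$statistic["rho"]), 1)
  expect_error(spearman_rho(rep(1, 5), 1:5), "undefined-correlation")

  # tie-free case equals the classical closed form and cor()
  set.seed(31)
  for (trial in 1:25) {
    x <- sample(100, 9); y <- sample(100, 9)
    rho <- unname(spearman_rho(x, y)$statistic["rho"])
    d <- rank(x) - rank(y)
    expect_equal(rho, 1 - 6 * sum(d^2) / (9 * (81 - 1)), tolerance = 1e-12)
    expect_equal(rho, stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  # exact permutation agrees in direction with the t approximation
  xe <- c(1, 2, 3, 4, 5, 6); ye <- c(2, 1, 4, 3, 6, 5)
  pe <- spearman_rho(xe, ye, exact = TRUE)
  expect_lte(pe$p.value, 1)
  expect_gte(pe$p.value, 0)
})

test_that("least-squares fit recovers exact lines and the cohort regression", {
  f <- linear_fit(1:10, 3 * (1:10) + 1)
  expect_equal(unname(f$statistic[c("slope", "intercept", "r.squared")]),
               c(3, 1, 1), tolerance = 1e-12)
  # residual orthogonality to x
  set.seed(2)
  x <- stats::rnorm(20); y <- 2 * x + stats::rnorm(20)
  ft <- stats::lm(y ~ x)
  expect_lt(abs(sum(stats::resid(ft) * x)), 1e-9)
  expect_error(linear_fit(rep(1, 5), 1:5), "degenerate-fit")

  rec <- load_table1()
  fit <- linear_fit(rec$motion3d_mm, rec$reduction_pct)
  expect_lt(abs(unname(fit$statistic["slope"]) - (-2.28)), 0.02)
})

test_that("tidy and glance methods expose statistics as tibbles", {
  w <- wilcoxon_signed_rank(c(3, 5, 9, 11), c(1, 2, 3, 4))
  td <- generics::tidy(w)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
  gl <- generics::glance(w)
  expect_equal(gl$n, 4)
})

test_that("the cohort report reproduces every summary quantity at once", {
  rep <- reproduce_table1_report()
  v <- function(q) rep$value[rep$quantity == q]
  expect_lt(abs(v("ptv_itv_median_cc") - 131.3), 0.1)
  expect_lt(abs(v("motion3d_min_mm") - 1.3), 0.1)
  expect_lt(abs(v("motion3d_patient1_mm") - 11.2), 0.1)
  expect_lt(abs(v("reduction_max_pct") - 39.2), 0.1)
  expect_lt(v("wilcoxon_ptv_p"), 0.01)
})

test_that("virtual cohorts are deterministic and respond to motion monotonically", {
  # two-patient zero-motion cohort: no paired differences anywhere
  cfgs <- lapply(1:2, function(i) {
    phantom_config(grid_shape = rep(32, 3),
                   motion_amplitude_mm = c(ap = 0, si = 0, lr = 0),
                   organs = scaled_organs(0.45), seed = i)
  })
  vc <- run_virtual_cohort(cfgs, sip = FALSE, four_d = FALSE)
  expect_equal(vc$patients$ptv_itv_cc, vc$patients$ptv_track_cc)
  met <- vc$metrics
  for (p in c("Dmean", "D95")) {
    a <- met[met$arm == "itv", ][[p]]
    b <- met[met$arm == "tracking", ][[p]]
    expect_equal(a, b, tolerance = 1e-9)
  }
  vc2 <- run_virtual_cohort(cfgs, sip = FALSE, four_d = FALSE)
  expect_identical(vc$metrics, vc2$metrics)

  # identical tumors with increasing rigid motion: |PTV reduction| grows
  red <- vapply(c(2, 4, 6, 8, 10, 12), function(a) {
    ph <- make_phantom(small_phantom_config(amp = c(ap = 0, si = a, lr = 0), n = 40,
                                            scale = 0.45))
    ssi <- build_structure_set(ph, "itv")
    sst <- build_structure_set(ph, "tracking")
    abs(ptv_reduction_percent(volume_cc(ssi$masks$ptv), volume_cc(sst$masks$ptv)))
  }, numeric(1))
  expect_true(all(diff(red) > 0))
})
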