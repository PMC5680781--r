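#' Load the bundled 12-patient reference cohort
#'
#' Reads the packaged cohort of pancreatic SBRT patients: planning target
#' volume of the motion-envelope (ITV) concept and of the tracking concept,
#' and per-axis respiratory motion amplitudes. On load the 3-D motion
#' magnitude is recomputed from the per-axis columns and cross-checked
#' against the printed column; a deviation beyond 0.15 mm (the worst-case
#' effect of the per-axis values being rounded to 1 d.p.) raises a
#' fixture-corruption error.
#'
#' @return Tibble with one row per patient: `patient`, `ptv_itv_cc`,
#'   `ptv_track_cc`, `ap_mm`, `si_mm`, `lr_mm`, `motion3d_mm` (printed,
#'   used for the motion statistics), `motion3d_recomputed_mm`, and the
#'   signed `reduction_pct` (negative = tracking PTV smaller).
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_motion_ptv.csv", package = "trackdose")
  if (path == "") stop("fixture-corruption error: cohort fixture not found")
  df <- utils::read.csv(path, comment.char = "#")
  if (nrow(df) != 12) stop("fixture-corruption error: expected 12 patients")
  rec <- motion_3d(df$ap_mm, df$si_mm, df$lr_mm)
  if (any(abs(rec - df$motion3d_mm) > 0.15)) {
    stop("fixture-corruption error: 3D motion column inconsistent with per-axis amplitudes")
  }
  tibble::tibble(
    patient = df$patient,
    ptv_itv_cc = df$ptv_itv_cc, ptv_track_cc = df$ptv_track_cc,
    ap_mm = df$ap_mm, si_mm = df$si_mm, lr_mm = df$lr_mm,
    motion3d_mm = df$motion3d_mm,
    motion3d_recomputed_mm = rec,
    reduction_pct = ptv_reduction_percent(df$ptv_itv_cc, df$ptv_track_cc)
  )
}

#' Cohort summary statistics
#'
#' Median (midpoint of the central order statistics), 25th/75th
#' percentiles (linear interpolation, type 7), mean and sample standard
#' deviation for each numeric column, plus the PTV-reduction statistics
#' (per-patient absolute percentages: mean, SD, min, max).
#'
#' @param records Cohort tibble from [load_table1()] (or compatible).
#' @return List with `columns` (tibble of per-column statistics) and
#'   `reduction` (one-row tibble).
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) < 1) stop("domain error: empty cohort")
  cols <- c("ptv_itv_cc", "ptv_track_cc", "ap_mm", "si_mm", "lr_mm", "motion3d_mm")
  cols <- intersect(cols, names(records))
  columns <- dplyr::bind_rows(lapply(cols, function(cn) {
    v <- records[[cn]]
    tibble::tibble(
      column = cn, median = stats::median(v),
      p25 = unname(stats::quantile(v, 0.25, type = 7)),
      p75 = unname(stats::quantile(v, 0.75, type = 7)),
      mean = mean(v), sd = stats::sd(v)
    )
  }))
  red <- if (all(c("ptv_itv_cc", "ptv_track_cc") %in% names(records))) {
    r <- abs(ptv_reduction_percent(records$ptv_itv_cc, records$ptv_track_cc))
    tibble::tibble(mean_pct = mean(r), sd_pct = stats::sd(r),
                   min_pct = min(r), max_pct = max(r))
  } else {
    tibble::tibble()
  }
  list(columns = columns, reduction = red)
}

#' Two-sided paired Wilcoxon signed-rank test (exact for small n)
#'
#' Implemented from first principles: zero differences are dropped, tied
#' absolute differences receive midranks, and the statistic is the sum of
#' ranks of the positive differences. For n <= 20 the two-sided p-value is
#' exact, from the full distribution of the statistic over all 2^n sign
#' assignments (computed by dynamic programming, identical to complete
#' enumeration); for larger n a normal approximation with continuity and
#' tie correction is used. Two-sided p = min(1, 2 * smaller tail).
#'
#' @param paired_a,paired_b Numeric vectors of equal length.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return A `stat_result` with `statistic` (V, rank sum of positive
#'   differences), `p.value`, `n` (non-zero pairs), `ties`, `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, exact_max = 20) {
  if (length(paired_a) != length(paired_b)) stop("paired vectors must have equal length")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("undefined-test error: all paired differences are zero")
  r <- rank(abs(d))
  ties <- anyDuplicated(abs(d)) > 0
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of V over all sign vectors; midranks doubled to integers
    r2 <- as.integer(round(2 * r))
    M <- sum(r2)
    f <- numeric(M + 1)      # f[w+1] = number of sign vectors with 2V = w
    f[1] <- 1
    for (rr in r2) {
      g <- numeric(M + 1)
      g[(rr + 1):(M + 1)] <- f[1:(M + 1 - rr)]
      f <- f + g
    }
    v2 <- as.integer(round(2 * V))
    lower <- sum(f[1:(v2 + 1)]) / 2^n
    upper <- sum(f[(v2 + 1):(M + 1)]) / 2^n
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  stat_result(statistic = c(V = V), p.value = p, n = n,
              method = paste0("Wilcoxon signed rank, ", method),
              ties = ties)
}

#' Spearman rank correlation with midranks
#'
#' Pearson correlation of the midranks of the two vectors; the two-sided
#' p-value uses the t approximation `t = rho * sqrt((n-2) / (1-rho^2))`
#' with n-2 degrees of freedom. For tie-free inputs this equals the
#' classical `1 - 6*sum(d^2)/(n(n^2-1))`. An exact permutation p-value is
#' available for small n.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exact Use full permutation enumeration for the p-value
#'   (only for n <= 8).
#' @return A `stat_result` with `statistic` (rho), `p.value`, `n`.
#' @export
spearman_rho <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 3) stop("spearman_rho: need at least 3 pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("undefined-correlation error: constant input vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stop("exact permutation only supported for n <= 8")
    perms <- permn_all(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx[p], ry))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "Spearman rank correlation, exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "Spearman rank correlation, t approximation"
  }
  stat_result(statistic = c(rho = rho), p.value = p, n = n, method = method,
              ties = anyDuplicated(x) > 0 || anyDuplicated(y) > 0)
}

permn_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permn_all(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- append(sub[i, ], n, after = pos - 1)
      row <- row + 1
    }
  }
  out
}

#' Ordinary least-squares line fit
#'
#' Slope, intercept and R-squared of `y ~ x` (via `stats::lm`), returned
#' as a `stat_result` for the motion-vs-reduction regression.
#'
#' @param x,y Numeric vectors, length >= 2, `x` not constant.
#' @return A `stat_result` with `statistic = c(slope, intercept, r.squared)`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) < 2) stop("linear_fit: need at least 2 points")
  if (length(unique(x)) < 2) stop("degenerate-fit error: constant x")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  stat_result(
    statistic = c(slope = unname(stats::coef(fit)[2]),
                  intercept = unname(stats::coef(fit)[1]),
                  r.squared = sm$r.squared),
    p.value = if (nrow(sm$coefficients) > 1 && length(x) > 2) sm$coefficients[2, 4] else NA_real_,
    n = length(x), method = "ordinary least squares", ties = FALSE
  )
}

stat_result <- function(statistic, p.value, n, method, ties = FALSE) {
  structure(list(statistic = statistic, p.value = p.value, n = n,
                 method = method, ties = ties),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s (n=%d): %s; p = %.4g\n", x$method, x$n,
              paste(sprintf("%s=%.4g", names(x$statistic), x$statistic),
                    collapse = ", "), x$p.value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.stat_result <- function(x, ...) {
  tibble::tibble(term = names(x$statistic), estimate = unname(x$statistic),
                 p.value = x$p.value, n = x$n, method = x$method)
}

#' @export
glance.stat_result <- function(x, ...) {
  tibble::tibble(p.value = x$p.value, n = x$n, ties = x$ties, method = x$method)
}

#' Reproduce every cohort-level statistic of the reference cohort
#'
#' Recomputes, from the packaged fixture alone, the PTV size summary, the
#' PTV-reduction statistics, the 3-D motion summary, the reduction-vs-motion
#' regression, the Spearman correlation and the paired Wilcoxon test of the
#' PTV sizes.
#'
#' @return Tibble with `quantity` and `value` columns (units embedded in
#'   the quantity names), of class `table1_report`.
#' @export
reproduce_table1_report <- function() {
  rec <- load_table1()
  sm <- summarize_cohort(rec)
  g <- function(col, stat) {
    sm$columns[[stat]][sm$columns$column == col]
  }
  fit <- linear_fit(rec$motion3d_mm, rec$reduction_pct)
  sp <- spearman_rho(rec$motion3d_mm, rec$reduction_pct)
  wx <- wilcoxon_signed_rank(rec$ptv_itv_cc, rec$ptv_track_cc)
  out <- tibble::tibble(
    quantity = c(
      "ptv_itv_median_cc", "ptv_itv_mean_cc", "ptv_itv_sd_cc",
      "ptv_track_median_cc", "ptv_track_mean_cc",
      "reduction_mean_pct", "reduction_sd_pct",
      "reduction_min_pct", "reduction_max_pct",
      "motion3d_min_mm", "motion3d_max_mm", "motion3d_mean_mm",
      "motion3d_patient1_mm",
      "fit_slope", "fit_intercept", "fit_r_squared",
      "spearman_rho", "spearman_p",
      "wilcoxon_ptv_p"
    ),
    value = c(
      g("ptv_itv_cc", "median"), g("ptv_itv_cc", "mean"), g("ptv_itv_cc", "sd"),
      g("ptv_track_cc", "median"), g("ptv_track_cc", "mean"),
      sm$reduction$mean_pct, sm$reduction$sd_pct,
      sm$reduction$min_pct, sm$reduction$max_pct,
      min(rec$motion3d_recomputed_mm), max(rec$motion3d_recomputed_mm),
      mean(rec$motion3d_recomputed_mm),
      rec$motion3d_recomputed_mm[rec$patient == 1],
      unname(fit$statistic["slope"]), unname(fit$statistic["intercept"]),
      unname(fit$statistic["r.squared"]),
      unname(sp$statistic["rho"]), sp$p.value,
      wx$p.value
    )
  )
  class(out) <- c("table1_report", class(out))
  out
}

#' Phantom configurations emulating the reference cohort
#'
#' One phantom configuration per patient of the bundled cohort, using that
#' patient's per-axis motion amplitudes as generator amplitudes. Organ
#' geometry is jittered per patient (seeded) so tumor sizes and OAR
#' distances vary across the virtual cohort.
#'
#' @param grid_shape Grid size (default 64^3 at 2 mm).
#' @param spacing_mm Voxel spacing (default 2).
#' @param jitter_mm Organ-position jitter SD (default 2 mm).
#' @param seed_offset Added to the patient number to form each config seed.
#' @return List of [phantom_config()] objects.
#' @export
cohort_configs_from_table1 <- function(grid_shape = c(64, 64, 64),
                                       spacing_mm = 2, jitter_mm = 2,
                                       seed_offset = 100L) {
  rec <- load_table1()
  lapply(seq_len(nrow(rec)), function(i) {
    phantom_config(
      grid_shape = grid_shape, spacing_mm = spacing_mm,
      motion_amplitude_mm = c(ap = rec$ap_mm[i], si = rec$si_mm[i],
                              lr = rec$lr_mm[i]),
      jitter_mm = jitter_mm, seed = seed_offset + rec$patient[i]
    )
  })
}

#' Run a virtual cohort through both planning arms
#'
#' For each configuration: generate the phantom, build both structure
#' sets, create and normalize both plans (with the overlap adjustment),
#' evaluate 3-D dose metrics, accumulate the 4-D dose of both arms and
#' evaluate 4-D metrics on the reference-phase structures.
#'
#' @param configs List of [phantom_config()] (default: the reference-cohort
#'   configurations).
#' @param sip Run the overlap (SIP) adjustment per plan (default TRUE).
#' @param four_d Also accumulate 4-D doses (default TRUE).
#' @param gantry_speed_deg_s Gantry speed for the 4-D segmentation.
#' @param progress Print per-patient progress to stderr.
#' @return List with `metrics` (tibble: one row per patient x arm x mode x
#'   structure with the seven dose parameters), `patients` (tibble of PTV
#'   volumes, motion amplitudes, objective flags), elements `phantoms` is
#'   not kept (memory).
#' @export
run_virtual_cohort <- function(configs = cohort_configs_from_table1(),
                               sip = TRUE, four_d = TRUE,
                               gantry_speed_deg_s = 3, progress = FALSE) {
  if (length(configs) < 2) stop("run_virtual_cohort: need at least 2 virtual patients")
  metrics <- list(); patients <- list()
  for (i in seq_along(configs)) {
    if (progress) message(sprintf("virtual patient %d/%d", i, length(configs)))
    ph <- make_phantom(configs[[i]])
    tr_itv <- plan_itv(ph, sip = sip)
    tr_trk <- plan_track(ph, sip = sip)
    amp <- motion_amplitudes(ph$cov_trajectory)
    m3 <- list(
      summarize_metrics(tr_itv$dose, tr_itv$structures, "3D"),
      summarize_metrics(tr_trk$dose, tr_trk$structures, "3D")
    )
    m4 <- list()
    if (four_d) {
      a_itv <- accumulate_4d(tr_itv, ph, gantry_speed_deg_s = gantry_speed_deg_s)
      a_trk <- accumulate_4d(tr_trk, ph, gantry_speed_deg_s = gantry_speed_deg_s)
      m4 <- list(
        summarize_metrics(a_itv$dose, tr_itv$structures, "4D", phantom = ph),
        summarize_metrics(a_trk$dose, tr_trk$structures, "4D", phantom = ph)
      )
    }
    mm <- dplyr::bind_rows(c(m3, m4))
    mm$patient <- i
    metrics[[i]] <- mm
    patients[[i]] <- tibble::tibble(
      patient = i,
      ptv_itv_cc = volume_cc(tr_itv$structures$masks$ptv),
      ptv_track_cc = volume_cc(tr_trk$structures$masks$ptv),
      ap_mm = amp$ap_mm, si_mm = amp$si_mm, lr_mm = amp$lr_mm,
      motion3d_mm = amp$motion3d_mm,
      itv_objectives_met = tr_itv$objectives_met,
      track_objectives_met = tr_trk$objectives_met
    )
  }
  list(metrics = dplyr::bind_rows(metrics),
       patients = dplyr::bind_rows(patients))
}

#' Arm comparison table for a virtual cohort
#'
#' Builds the per-parameter comparison of the two motion-management arms:
#' for each evaluation mode (3-D / 4-D), structure and dose parameter, the
#' median of the ITV arm, the median and quartiles of the paired
#' difference (tracking - ITV), the two-sided paired Wilcoxon p-value, and
#' the Spearman correlation of the difference with 3-D tumor motion.
#'
#' @param cohort Output of [run_virtual_cohort()].
#' @param parameters Dose parameters to tabulate.
#' @return Tibble with one row per mode x structure x parameter.
#' @export
summarize_virtual_cohort <- function(cohort,
                                     parameters = c("Dmean", "Dmax", "Dmin",
                                                    "D95", "D2", "D98", "D0.1cc")) {
  met <- cohort$metrics
  motion <- cohort$patients$motion3d_mm[order(cohort$patients$patient)]
  rows <- list()
  for (md in unique(met$mode)) {
    for (st in unique(met$structure[met$mode == md])) {
      for (pp in parameters) {
        a <- met[met$mode == md & met$structure == st & met$arm == "itv", ]
        b <- met[met$mode == md & met$structure == st & met$arm == "tracking", ]
        if (nrow(a) == 0 || nrow(b) == 0) next
        a <- a[order(a$patient), ]; b <- b[order(b$patient), ]
        va <- a[[pp]]; vb <- b[[pp]]
        if (all(is.na(va)) || all(is.na(vb))) next
        diff <- vb - va
        wp <- tryCatch(wilcoxon_signed_rank(vb, va)$p.value, error = function(e) NA_real_)
        sp <- tryCatch(spearman_rho(motion[a$patient], diff),
                       error = function(e) NULL)
        rows[[length(rows) + 1]] <- tibble::tibble(
          mode = md, structure = st, parameter = pp,
          median_itv = stats::median(va),
          median_diff = stats::median(diff),
          p25_diff = unname(stats::quantile(diff, 0.25)),
          p75_diff = unname(stats::quantile(diff, 0.75)),
          wilcoxon_p = wp,
          spearman_rho = if (is.null(sp)) NA_real_ else unname(sp$statistic["rho"]),
          spearman_p = if (is.null(sp)) NA_real_ else sp$p.value
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
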