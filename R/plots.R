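#' Plot a cumulative DVH curve
#'
#' @param object A `dvh_curve` from [cumulative_dvh()].
#' @param ... Further curves to overlay (named arguments become legend
#'   labels).
#' @return A ggplot object.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  extra <- list(...)
  curves <- c(list(object), extra[vapply(extra, inherits, logical(1), "dvh_curve")])
  labs <- vapply(seq_along(curves), function(i) {
    nm <- if (i == 1) attr(object, "structure") else names(extra)[i - 1]
    if (is.null(nm) || nm == "") attr(curves[[i]], "structure") else nm
  }, character(1))
  df <- dplyr::bind_rows(lapply(seq_along(curves), function(i) {
    tibble::tibble(dose_gy = curves[[i]]$dose_gy,
                   volume_fraction = curves[[i]]$volume_fraction,
                   structure = labs[i])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_gy,
                                   y = 100 * .data$volume_fraction,
                                   colour = .data$structure)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of PTV reduction against 3-D tumor motion with the OLS line
#'
#' @param records Cohort tibble from [load_table1()] (needs
#'   `motion3d_mm` and `reduction_pct`).
#' @return A ggplot object.
#' @export
plot_motion_reduction <- function(records) {
  fit <- linear_fit(records$motion3d_mm, records$reduction_pct)
  sl <- unname(fit$statistic["slope"]); ic <- unname(fit$statistic["intercept"])
  ggplot2::ggplot(records, ggplot2::aes(x = .data$motion3d_mm,
                                        y = .data$reduction_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = sl, intercept = ic, linetype = 2) +
    ggplot2::labs(
      x = "3D tumor motion (mm)", y = "PTV reduction (%)",
      subtitle = sprintf("y = %.2f x %+.2f,  R² = %.3f", sl, ic,
                         unname(fit$statistic["r.squared"]))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
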