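#' Plot the refocus-distance calibration
#'
#' Scatter of the calibration cells' coarse autofocus distances against
#' lateral position, with the fitted quadratic and a one-residual-standard-
#' deviation band (the spread used by the three-depth refinement).
#'
#' @param calib A [calibrate_focus()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_focus_calibration <- function(calib, ...) {
  stopifnot(inherits(calib, "focus_calibration"))
  dat <- tibble::tibble(
    x_full = calib$model$model$x_full,
    d_um = calib$model$model$d_um
  )
  xs <- seq(min(dat$x_full), max(dat$x_full), length.out = 200)
  fitted <- tibble::tibble(x_full = xs, d_um = predict_focus(calib, xs))
  s <- calib$residual_std_um
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x_full, y = .data$d_um)) +
    ggplot2::geom_ribbon(
      data = fitted,
      ggplot2::aes(ymin = .data$d_um - s, ymax = .data$d_um + s),
      fill = "grey80"
    ) +
    ggplot2::geom_line(data = fitted, colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "lateral position (full-res column)",
                  y = "refocus distance (um)",
                  title = "Refocus calibration d(x)") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Dot plot of the mean error of each metric before and after real-time
#' refocusing (SSIM excluded: it is a similarity, not an error).
#'
#' @param object An `hc_evaluation` from [compare_populations()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hc_evaluation <- function(object, ...) {
  df <- object[object$metric != "ssim", ]
  long <- tibble::tibble(
    metric = rep(df$metric, 2),
    stage = rep(c("before", "after"), each = nrow(df)),
    value = c(df$mean_before, df$mean_after)
  )
  long$stage <- factor(long$stage, levels = c("before", "after"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$metric,
                                     colour = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean error (log scale)", y = NULL,
                  colour = NULL,
                  title = "Refocusing error before/after, vs fine refocus") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' One-row summary of an evaluation report
#'
#' @param x An `hc_evaluation` tibble.
#' @param ... Unused.
#' @return A tibble with `n_cells`, `mean_ssim_before`, `mean_ssim_after`
#'   and the largest mean improvement factor across error metrics.
#' @export
glance.hc_evaluation <- function(x, ...) {
  tibble::tibble(
    n_cells = attr(x, "n_cells"),
    mean_ssim_before = x$mean_before[x$metric == "ssim"],
    mean_ssim_after = x$mean_after[x$metric == "ssim"],
    best_mean_factor = max(x$mean_factor, na.rm = TRUE)
  )
}
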