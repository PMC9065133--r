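#' Plot a pairwise-difference density
#'
#' Density of the pairwise intensity differences with the zero-exclusion
#' window shaded and the positive-side local maxima marked (filled points
#' for qualifying peaks).
#'
#' @param object A `pdd_density` from [estimate_density()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pdd_density
#' @export
autoplot.pdd_density <- function(object, ...) {
  den <- object$density
  peaks <- object$peaks
  p <- ggplot2::ggplot(den, ggplot2::aes(x = .data$d, y = .data$density)) +
    ggplot2::annotate("rect", xmin = -object$d_min, xmax = object$d_min,
                      ymin = -Inf, ymax = Inf, alpha = 0.1) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "pairwise intensity difference (arb. units)",
      y = "density"
    )
  if (nrow(peaks) > 0L) {
    p <- p + ggplot2::geom_point(
      data = peaks,
      ggplot2::aes(x = .data$position, y = .data$height,
                   shape = .data$qualifying),
      size = 2
    ) +
      ggplot2::scale_shape_manual(
        values = c(`TRUE` = 16, `FALSE` = 1), name = "qualifying"
      )
  }
  p
}

#' Plot a step-count fit
#'
#' Raw and median-smoothed trace with the detected downward transitions
#' marked; the subtitle reports the step count and unit step size.
#'
#' @param object A `step_fit` from [estimate_step_count()].
#' @param time_s Optional time axis (seconds); frame index used otherwise.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot step_fit
#' @export
autoplot.step_fit <- function(object, time_s = NULL, ...) {
  n <- object$n_frames
  t <- time_s %||% (seq_len(n) - 1)
  df <- tibble(t = t, smoothed = object$smoothed)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$smoothed)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (is.null(time_s)) "frame" else "time (s)",
      y = "Surf649 intensity (arb. units)",
      subtitle = sprintf(
        "%d photobleaching step%s%s", object$k_steps,
        if (object$k_steps == 1L) "" else "s",
        if (is.na(object$step_size_estimate)) "" else
          sprintf(", unit step %.3g", object$step_size_estimate)
      )
    )
  if (nrow(object$transitions) > 0L) {
    tr <- object$transitions
    p <- p + ggplot2::geom_vline(
      xintercept = t[tr$frame + 1L], linetype = "dashed", alpha = 0.5
    )
  }
  p
}

#' Box-and-whisker plot of per-condition stoichiometry
#'
#' Reproduces the reporting convention for photobleaching-step counts:
#' boxes between the 25th and 75th percentiles with the median line,
#' whiskers at the 10th and 90th percentiles, and outliers beyond the
#' whiskers as closed circles.
#'
#' @param object A `condition_summary` from [summarize_conditions()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot condition_summary
#' @export
autoplot.condition_summary <- function(object, ...) {
  df <- as_tibble(object)
  out <- tidyr::unnest(df[, c("condition", "outliers")], "outliers")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$p10, ymax = .data$p90), width = 0.2
    ) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$q25, ymax = .data$q75),
      width = 0.5, fill = "grey90"
    ) +
    ggplot2::geom_point(
      data = out, ggplot2::aes(y = .data$outliers), size = 1.5
    ) +
    ggplot2::labs(
      x = NULL, y = "LEDGF/p75 photobleaching steps per intasome"
    )
}

#' Overlay detections on a field image
#'
#' @param image 2-D matrix (e.g. the processed Cy3 temporal mean).
#' @param spots Detections from [detect_spots()].
#' @return A ggplot showing the image raster with detection apertures.
#' @export
plot_detections <- function(image, spots) {
  df <- expand.grid(y = seq_len(nrow(image)) - 1L,
                    x = seq_len(ncol(image)) - 1L)
  df$value <- as.vector(image)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(
      data = spots, ggplot2::aes(x = .data$x_px, y = .data$y_px),
      shape = 1, colour = "red",
      size = 2
    ) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "arb. units") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}
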