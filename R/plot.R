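#' Plot a pressure trace
#'
#' Line plot of the trace, thinned to at most `max_points` samples so that
#' hour-long 1 kHz traces plot quickly.
#'
#' @param object A [pressure_trace()].
#' @param max_points Maximum points drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pressure_trace <- function(object, max_points = 20000, ...) {
  step <- max(1L, floor(nrow(object) / max_points))
  dat <- object[seq(1L, nrow(object), by = step), ]
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_s, .data$pressure_mmhg)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "pressure (mmHg)",
      title = sprintf("%s line pressure", trace_channel(object))
    )
}

#' Plot a windowed flow series
#'
#' @param object A [flow_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$flow_ml_min)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "flow (ml/min)",
                  title = "Pump flow estimate")
}

#' Plot per-point calibration values for one session
#'
#' @param object A [session_calibration()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.session_calibration <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$time_s, .data$c_value)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$c_session, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(
      x = "time (s)", y = "lumped parameter C",
      title = sprintf("Session %s: C = %.2f", object$session_id,
                      object$c_session)
    )
}

#' Plot a continuous MAP estimate
#'
#' @param object A `bp_estimate` from [continuous_bp()].
#' @param cuffs Optional [cuff_measurements()] tibble overlaid as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bp_estimate <- function(object, cuffs = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$map_mmhg)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "MAP (mmHg)",
                  title = "Continuous brachial MAP estimate")
  if (!is.null(cuffs) && nrow(cuffs) > 0) {
    p <- p + ggplot2::geom_point(
      data = cuffs, ggplot2::aes(.data$time_s, .data$map_mmhg),
      colour = "firebrick", size = 2
    )
  }
  p
}

#' Plot a cuff-MAP vs arterial-pressure fit
#'
#' @param object A `bp_fit` from [fit_map_vs_arterial()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bp_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$p2_mmhg, .data$pb_mmhg)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "arterial line pressure (mmHg)", y = "brachial cuff MAP (mmHg)",
      title = sprintf("Pb = %.2f P2 + %.0f (R² %.3f)", object$slope,
                      object$intercept, object$r_squared)
    )
}

#' Plot lumped-parameter values grouped by needle gauge
#'
#' @param object A `gauge_c_summary` from [group_c_by_gauge()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gauge_c_summary <- function(object, ...) {
  pts <- tidyr::unnest(
    dplyr::select(as_tibble(object), "gauge", "points"), "points",
    names_sep = "_"
  )
  core <- dplyr::select(as_tibble(object), "gauge", "c_core_mean")
  ggplot2::ggplot(pts, ggplot2::aes(.data$gauge, .data$points_c_value)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$points_is_outlier),
                         width = 0.1, height = 0) +
    ggplot2::geom_point(data = core,
                        ggplot2::aes(.data$gauge, .data$c_core_mean),
                        shape = 3, size = 4, colour = "black",
                        inherit.aes = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick"),
                                 name = "outlier") +
    ggplot2::labs(x = "needle gauge set", y = "lumped parameter C",
                  title = "C grouped by needle gauge (+ = core mean)")
}
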