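#' Estimate brachial MAP from line pressure, flow and C
#'
#' The exact algebraic inverse of [c_from_point()]:
#' `Pb = p2 + 0.5 * (flow / a2)^2 * C / unit_scale`. With `C = 0` the
#' estimate degenerates to the line pressure itself.
#'
#' @param c_value Lumped parameter C (units of [c_unit_scale()] by default).
#' @param p2_mmhg Filtered arterial-line pressure, mmHg.
#' @param flow_ml_min Blood flow, ml/min (>= 0).
#' @param a2_mm2 Arterial needle area, mm^2 (> 0).
#' @param unit_scale See [c_unit_scale()].
#' @return Estimated brachial MAP, mmHg (vectorised).
#' @export
#' @examples
#' a2 <- needle_spec(14)$area_mm2
#' cc <- c_from_point(95, -120, 325, a2)
#' estimate_map(cc, -120, 325, a2) # exactly 95
estimate_map <- function(c_value, p2_mmhg, flow_ml_min, a2_mm2,
                         unit_scale = c_unit_scale()) {
  if (any(!is.finite(flow_ml_min)) || any(flow_ml_min < 0)) {
    abort_linebp("invalid_parameter", "`flow_ml_min` must be >= 0.")
  }
  if (any(!is.finite(a2_mm2)) || any(a2_mm2 <= 0)) {
    abort_linebp("invalid_parameter", "`a2_mm2` must be > 0.")
  }
  p2_mmhg + 0.5 * (flow_ml_min / a2_mm2)^2 * c_value / unit_scale
}

#' Continuous brachial MAP estimate over a session
#'
#' Reconstructs brachial MAP at the flow-estimate cadence (1 Hz with default
#' windowing) by applying [estimate_map()] to the moving-averaged arterial
#' pressure and the windowed flow estimates. Windows without a flow estimate
#' (pump off) leave gaps. The default policy uses one fixed C for the whole
#' session (normally the session mean from [session_calibration()]); the
#' `"causal"` policy instead uses, at each time, the running mean of the
#' calibration points observed so far, emulating real-time operation in
#' which C is learned as cuff readings arrive (no estimate before the first
#' point).
#'
#' @param session A [session_record()].
#' @param c_value Fixed session C; defaults to `calibration$c_session` when
#'   a calibration is supplied.
#' @param flow A [flow_series()].
#' @param filtered_arterial Moving-averaged arterial [pressure_trace()].
#' @param c_policy `"fixed"` (default) or `"causal"`.
#' @param calibration A [session_calibration()]; required for the causal
#'   policy.
#' @param unit_scale See [c_unit_scale()].
#' @return A tibble of class `bp_estimate` with columns `time_s`,
#'   `map_mmhg`, `p2_mmhg`, `flow_ml_min`, `c_value`.
#' @export
continuous_bp <- function(session, c_value = NULL, flow, filtered_arterial,
                          c_policy = c("fixed", "causal"),
                          calibration = NULL,
                          unit_scale = c_unit_scale()) {
  stopifnot(inherits(session, "session_record"), is.data.frame(flow),
            is_pressure_trace(filtered_arterial))
  c_policy <- match.arg(c_policy)
  if (nrow(flow) == 0) {
    abort_linebp("no_estimate", "flow series is empty: no windows with a detected pump signal.")
  }
  if (c_policy == "fixed") {
    if (is.null(c_value)) {
      if (is.null(calibration)) {
        abort_linebp("invalid_parameter", "supply `c_value` or a `calibration` for the fixed policy.")
      }
      c_value <- calibration$c_session
    }
    c_t <- rep(c_value, nrow(flow))
  } else {
    if (is.null(calibration)) {
      abort_linebp("invalid_parameter", "the causal policy requires a `calibration`.")
    }
    pts <- calibration$points
    c_t <- purrr::map_dbl(flow$time_s, function(t) {
      seen <- pts$c_value[pts$time_s <= t]
      if (length(seen) == 0) NA_real_ else mean(seen)
    })
  }
  span <- c(trace_start_time(filtered_arterial), trace_end_time(filtered_arterial))
  keep <- !is.na(c_t) & flow$time_s >= span[1] & flow$time_s <= span[2]
  flow <- flow[keep, ]
  c_t <- c_t[keep]
  if (nrow(flow) == 0) {
    abort_linebp("no_estimate", "no flow estimate overlaps the filtered trace with an available C.")
  }
  a2 <- session$arterial_needle$area_mm2
  p2 <- value_at_time(filtered_arterial, flow$time_s)
  out <- tibble(
    time_s = flow$time_s,
    map_mmhg = estimate_map(c_t, p2, flow$flow_ml_min, a2, unit_scale),
    p2_mmhg = p2,
    flow_ml_min = flow$flow_ml_min,
    c_value = c_t
  )
  structure(out,
    c_policy = c_policy,
    session_id = session$session_id,
    class = c("bp_estimate", class(out))
  )
}

#' Least-squares fit of cuff MAP against arterial line pressure
#'
#' Ordinary least squares of `pb_mmhg` on `p2_mmhg`, summarising the
#' quasi-linear relation between the filtered arterial-line pressure and
#' brachial MAP across measurement pairs.
#'
#' @param points A data frame with columns `p2_mmhg` and `pb_mmhg` (>= 3
#'   rows with variance in `p2_mmhg`).
#' @return An object of class `bp_fit` with fields `slope`, `intercept`,
#'   `rmse` (root mean squared residual), `r_squared`, `p_value` (slope),
#'   `n_points`, plus the underlying `lm` fit and the points.
#' @export
fit_map_vs_arterial <- function(points) {
  stopifnot(is.data.frame(points))
  if (!all(c("p2_mmhg", "pb_mmhg") %in% names(points))) {
    abort_linebp("invalid_parameter", "`points` needs columns `p2_mmhg` and `pb_mmhg`.")
  }
  points <- tidyr::drop_na(as_tibble(points[, c("p2_mmhg", "pb_mmhg")]))
  n <- nrow(points)
  if (n < 3) {
    abort_linebp("degenerate_fit", sprintf("need at least 3 points, got %d.", n))
  }
  if (stats::var(points$p2_mmhg) == 0) {
    abort_linebp("degenerate_fit", "zero variance in `p2_mmhg`.")
  }
  m <- lm(pb_mmhg ~ p2_mmhg, data = points)
  res <- residuals(m)
  sst <- sum((points$pb_mmhg - mean(points$pb_mmhg))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 0
  # summary.lm warns on essentially perfect fits; rmse/r^2 are computed
  # directly above, so the warning carries no information here
  cf <- suppressWarnings(summary(m)$coefficients)
  p_slope <- if (nrow(cf) >= 2 && is.finite(cf[2, 4])) cf[2, 4] else NA_real_
  structure(
    list(
      slope = unname(coef(m)[2]),
      intercept = unname(coef(m)[1]),
      rmse = sqrt(mean(res^2)),
      r_squared = r2,
      p_value = p_slope,
      n_points = n,
      model = m,
      points = points
    ),
    class = "bp_fit"
  )
}

#' @export
print.bp_fit <- function(x, ...) {
  cat(sprintf(
    "<bp_fit> Pb = %.3f * P2 + %.1f  (rmse %.2f, R^2 %.3f, n %d)\n",
    x$slope, x$intercept, x$rmse, x$r_squared, x$n_points
  ))
  invisible(x)
}

#' @export
tidy.bp_fit <- function(x, ...) {
  cf <- suppressWarnings(summary(x$model)$coefficients)
  tibble(
    term = c("intercept", "p2_mmhg"),
    estimate = c(x$intercept, x$slope),
    std.error = cf[, 2],
    statistic = cf[, 3],
    p.value = cf[, 4]
  )
}

#' @export
glance.bp_fit <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept, rmse = x$rmse,
    r.squared = x$r_squared, p.value = x$p_value, nobs = x$n_points
  )
}

#' Pooled vs per-session-compensated regression
#'
#' Quantifies how much of the scatter in the pooled cuff-MAP vs
#' arterial-pressure relation is attributable to within-session variation of
#' the lumped parameter. The pooled fit regresses the observed cuff MAP on
#' the filtered arterial pressure across all sessions. The compensated fit
#' replaces each point's cuff MAP with the prediction recomputed from the
#' session-mean C ([estimate_map()] with `c_session`), i.e. the scatter
#' re-expressed with within-session C variation (and cuff measurement noise)
#' removed, and regresses those on the same arterial pressures. When every
#' point shares one constant C the two fits coincide; otherwise the
#' compensated R^2 is at least the pooled one while the slope should move
#' little.
#'
#' @param calibrations A list of [session_calibration()] objects (>= 2
#'   sessions, each with >= 2 points).
#' @return An object of class `bp_fit_pair`: list with elements `pooled` and
#'   `compensated`, both [fit_map_vs_arterial()] results.
#' @export
compensated_fit <- function(calibrations) {
  stopifnot(is.list(calibrations))
  calibrations <- calibrations[!purrr::map_lgl(calibrations, is.null)]
  if (length(calibrations) < 2) {
    abort_linebp("invalid_parameter", "need at least 2 session calibrations.")
  }
  if (any(purrr::map_int(calibrations, ~ nrow(.x$points)) < 2)) {
    abort_linebp("invalid_parameter", "every session needs at least 2 calibration points.")
  }
  pooled_pts <- purrr::map_dfr(calibrations, function(cal) {
    tibble(p2_mmhg = cal$points$p2_mmhg, pb_mmhg = cal$points$pb_mmhg)
  })
  comp_pts <- purrr::map_dfr(calibrations, function(cal) {
    p <- cal$points
    tibble(
      p2_mmhg = p$p2_mmhg,
      pb_mmhg = estimate_map(cal$c_session, p$p2_mmhg, p$flow_ml_min,
                             p$a2_mm2, cal$unit_scale)
    )
  })
  structure(
    list(
      pooled = fit_map_vs_arterial(pooled_pts),
      compensated = fit_map_vs_arterial(comp_pts)
    ),
    class = "bp_fit_pair"
  )
}

#' @export
print.bp_fit_pair <- function(x, ...) {
  cat("pooled:      "); print(x$pooled)
  cat("compensated: "); print(x$compensated)
  invisible(x)
}

#' @export
glance.bp_fit_pair <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$pooled), fit = "pooled", .before = 1),
    dplyr::mutate(glance(x$compensated), fit = "compensated", .before = 1)
  )
}

#' @export
tidy.bp_fit_pair <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$pooled), fit = "pooled", .before = 1),
    dplyr::mutate(tidy(x$compensated), fit = "compensated", .before = 1)
  )
}
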