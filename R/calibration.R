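#' Lumped parameter C from one measurement quartet
#'
#' Computes the Bernoulli lumped parameter from one paired observation of
#' cuff MAP (`pb`), filtered arterial-line pressure (`p2`), line flow and
#' arterial-needle area:
#' `C = unit_scale * 2 * (pb - p2) / (flow / a2)^2`.
#' With the default `unit_scale` ([c_unit_scale()]), `flow / a2` is treated
#' as a velocity and C is reported in 10^3 kg/m^3, the scale on which
#' clinically observed values fall between roughly 5 and 11. `C > 0` in the
#' physiological case (`pb` positive, `p2` negative under pump suction); C
#' absorbs unmodelled geometry, viscosity, density and access effects.
#'
#' @param pb_mmhg Brachial cuff MAP, mmHg.
#' @param p2_mmhg Filtered arterial-line pressure at the cuff time, mmHg.
#' @param flow_ml_min Blood flow, ml/min (> 0).
#' @param a2_mm2 Arterial needle cross-sectional area, mm^2 (> 0).
#' @param unit_scale Unit conversion constant; see [c_unit_scale()]. Pass 1
#'   for the raw canonical-unit ratio.
#' @return The lumped parameter C (vectorised).
#' @seealso [estimate_map()], the exact algebraic inverse.
#' @export
#' @examples
#' c_from_point(100, -150, 325, needle_spec(14)$area_mm2)
c_from_point <- function(pb_mmhg, p2_mmhg, flow_ml_min, a2_mm2,
                         unit_scale = c_unit_scale()) {
  if (any(!is.finite(flow_ml_min)) || any(flow_ml_min <= 0)) {
    abort_linebp("invalid_parameter", "`flow_ml_min` must be > 0 (C is undefined at zero flow).")
  }
  if (any(!is.finite(a2_mm2)) || any(a2_mm2 <= 0)) {
    abort_linebp("invalid_parameter", "`a2_mm2` must be > 0.")
  }
  unit_scale * 2 * (pb_mmhg - p2_mmhg) / (flow_ml_min / a2_mm2)^2
}

#' Calibrate the lumped parameter over one session
#'
#' Builds one calibration point per cuff reading that falls inside the
#' pumped, flow-estimable span of the session: the cuff MAP is paired with
#' the moving-averaged arterial pressure at the cuff time
#' ([value_at_time()]) and the nearest preceding flow estimate, and C is
#' computed with [c_from_point()]. Cuff readings with no preceding flow
#' estimate or outside the filtered-trace span are skipped with a recorded
#' reason. The session parameter `c_session` is the unweighted mean of the
#' per-point values (the robust `median` alternative is available via
#' `aggregate`), reported with its dispersion.
#'
#' @param session A [session_record()].
#' @param flow A [flow_series()] for the session.
#' @param filtered_arterial The moving-averaged arterial [pressure_trace()].
#' @param aggregate `"mean"` (default) or `"median"`.
#' @param unit_scale See [c_from_point()].
#' @return An object of class `session_calibration`: list with `points`
#'   (tibble: `time_s`, `pb_mmhg`, `p2_mmhg`, `flow_ml_min`, `a2_mm2`,
#'   `c_value`), `skipped` (tibble: `time_s`, `reason`), `c_session`, `c_sd`,
#'   `c_range`, `gauge_label`, `session_id`.
#' @export
session_calibration <- function(session, flow, filtered_arterial,
                                aggregate = c("mean", "median"),
                                unit_scale = c_unit_scale()) {
  stopifnot(inherits(session, "session_record"), is.data.frame(flow),
            is_pressure_trace(filtered_arterial))
  aggregate <- match.arg(aggregate)
  a2 <- session$arterial_needle$area_mm2
  span <- c(trace_start_time(filtered_arterial),
            trace_end_time(filtered_arterial))

  pts <- list()
  skipped <- list()
  for (i in seq_len(nrow(session$cuffs))) {
    cuff <- session$cuffs[i, ]
    t <- cuff$time_s
    if (t < span[1] || t > span[2]) {
      skipped[[length(skipped) + 1]] <-
        tibble(time_s = t, reason = "outside filtered-trace span")
      next
    }
    prior <- flow$time_s <= t + 1e-9
    if (!any(prior)) {
      skipped[[length(skipped) + 1]] <-
        tibble(time_s = t, reason = "no flow estimate at or before cuff time")
      next
    }
    fl <- flow$flow_ml_min[max(which(prior))]
    p2 <- value_at_time(filtered_arterial, t)
    pts[[length(pts) + 1]] <- tibble(
      time_s = t, pb_mmhg = cuff$map_mmhg, p2_mmhg = p2,
      flow_ml_min = fl, a2_mm2 = a2,
      c_value = c_from_point(cuff$map_mmhg, p2, fl, a2, unit_scale)
    )
  }
  points <- dplyr::bind_rows(pts)
  skipped <- dplyr::bind_rows(skipped)
  if (nrow(skipped) == 0) skipped <- tibble(time_s = double(), reason = character())
  if (nrow(points) == 0) {
    abort_linebp("no_calibration",
      "no usable cuff reading falls within the pumped, flow-estimable span.")
  }
  c_session <- if (aggregate == "mean") mean(points$c_value) else median(points$c_value)
  structure(
    list(
      points = points,
      skipped = skipped,
      c_session = c_session,
      c_sd = if (nrow(points) > 1) sd(points$c_value) else NA_real_,
      c_range = range(points$c_value),
      gauge_label = session$gauge_set,
      session_id = session$session_id,
      unit_scale = unit_scale
    ),
    class = "session_calibration"
  )
}

#' @export
print.session_calibration <- function(x, ...) {
  cat(sprintf(
    "<session_calibration> %s (gauge set %s): %d points, C = %.3f (sd %.3f), %d skipped\n",
    x$session_id, x$gauge_label, nrow(x$points), x$c_session,
    x$c_sd, nrow(x$skipped)
  ))
  invisible(x)
}

#' Summarise lumped-parameter values by needle gauge
#'
#' Pools the per-point C values of several session calibrations by gauge
#' label and summarises each group: all point values, their mean, the core
#' (non-outlier) mean and range, and the outliers flagged by the
#' median +/- `k_mad` * MAD rule. Needle gauge drives the available needle
#' area and hence the pressure gap, so the core means rise with gauge
#' number; sessions from immature or problematic vascular access typically
#' surface here as outliers.
#'
#' @param calibrations A list of [session_calibration()] objects (a single
#'   object is accepted).
#' @param k_mad Outlier threshold in MAD units (default 3).
#' @return A tibble of class `gauge_c_summary`, ordered by gauge, with
#'   columns `gauge`, `n_sessions`, `n_points`, `c_mean`, `c_core_mean`,
#'   `core_low`, `core_high`, `n_outliers` and list-column `points`
#'   (per-point tibbles with an `is_outlier` flag).
#' @export
group_c_by_gauge <- function(calibrations, k_mad = 3) {
  if (inherits(calibrations, "session_calibration")) {
    calibrations <- list(calibrations)
  }
  stopifnot(all(purrr::map_lgl(calibrations, inherits, "session_calibration")))
  points <- purrr::map_dfr(calibrations, function(cal) {
    dplyr::mutate(cal$points,
      gauge = cal$gauge_label, session_id = cal$session_id,
      .before = 1
    )
  })
  out <- points |>
    dplyr::group_by(.data$gauge) |>
    dplyr::group_modify(function(g, key) {
      med <- median(g$c_value)
      dev <- mad(g$c_value)
      is_out <- if (dev > 0) abs(g$c_value - med) > k_mad * dev else
        rep(FALSE, nrow(g))
      core <- g$c_value[!is_out]
      tibble(
        n_sessions = dplyr::n_distinct(g$session_id),
        n_points = nrow(g),
        c_mean = mean(g$c_value),
        c_core_mean = mean(core),
        core_low = min(core),
        core_high = max(core),
        n_outliers = sum(is_out),
        points = list(dplyr::mutate(g, is_outlier = is_out))
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gauge)
  structure(out,
    k_mad = k_mad,
    class = c("gauge_c_summary", class(out))
  )
}
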