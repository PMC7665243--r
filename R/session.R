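#' Dialysis needle specification
#'
#' Describes an access needle by gauge and inner diameter. Gauges 14, 15 and
#' 16 have default inner diameters (1.60, 1.37, 1.19 mm); any other gauge
#' must be given `inner_diameter_mm` explicitly. The cross-sectional area
#' `area_mm2` is derived as `pi * (ID / 2)^2` and is the A2 term of the
#' Bernoulli calibration when the needle is on the arterial line.
#'
#' @param gauge Needle gauge (14, 15, 16 or other).
#' @param inner_diameter_mm Inner diameter in mm; required when the gauge has
#'   no table default, otherwise overrides it.
#' @return A list of class `needle_spec` with fields `gauge`,
#'   `inner_diameter_mm`, `area_mm2`.
#' @export
#' @examples
#' needle_spec(14)
#' needle_spec(17, inner_diameter_mm = 1.1)
needle_spec <- function(gauge, inner_diameter_mm = NULL) {
  if (is.null(inner_diameter_mm)) {
    inner_diameter_mm <- gauge_inner_diameter(gauge)
    if (is.na(inner_diameter_mm)) {
      abort_linebp("invalid_parameter", sprintf(
        "gauge %s has no default inner diameter; supply `inner_diameter_mm`.",
        as.character(gauge)
      ))
    }
  }
  if (!is.numeric(inner_diameter_mm) || inner_diameter_mm <= 0) {
    abort_linebp("invalid_parameter", "`inner_diameter_mm` must be positive.")
  }
  structure(
    list(
      gauge = gauge,
      inner_diameter_mm = inner_diameter_mm,
      area_mm2 = pi * (inner_diameter_mm / 2)^2
    ),
    class = "needle_spec"
  )
}

#' Peristaltic pump geometry
#'
#' Line radius `r`, effective in-pump line length `Ln` and lobe count used to
#' convert pump rotation frequency to volumetric flow: one rotation displaces
#' `pi * r^2 * Ln` of line volume. Defaults (r = 4 mm, Ln = 107.8 mm, 2
#' lobes) describe a standard 8 mm dialysis line for which 1 rev/s
#' corresponds to about 325 ml/min.
#'
#' @param line_radius_mm Radius of the line within the pump, mm.
#' @param effective_length_mm Effective length of line within the pump, mm.
#' @param lobe_count Number of pump lobes (integer >= 1, typically 2).
#' @return A list of class `pump_geometry`.
#' @export
pump_geometry <- function(line_radius_mm = 4,
                          effective_length_mm = 107.8,
                          lobe_count = 2L) {
  if (!is.numeric(line_radius_mm) || line_radius_mm <= 0 ||
      !is.numeric(effective_length_mm) || effective_length_mm <= 0) {
    abort_linebp("invalid_parameter", "pump radius and effective length must be positive.")
  }
  if (!is.numeric(lobe_count) || lobe_count < 1 || lobe_count != round(lobe_count)) {
    abort_linebp("invalid_parameter", "`lobe_count` must be an integer >= 1.")
  }
  structure(
    list(
      line_radius_mm = line_radius_mm,
      effective_length_mm = effective_length_mm,
      lobe_count = as.integer(lobe_count)
    ),
    class = "pump_geometry"
  )
}

#' Brachial cuff measurements table
#'
#' Validates a set of intermittent arm-cuff readings. Times are seconds from
#' session start on the same axis as the pressure traces; MAP is the
#' calibrated quantity.
#'
#' @param time_s Measurement times, seconds from session start.
#' @param systolic_mmhg,diastolic_mmhg,map_mmhg Cuff pressures, mmHg.
#' @return A tibble with one row per reading.
#' @export
cuff_measurements <- function(time_s, systolic_mmhg, diastolic_mmhg, map_mmhg) {
  out <- tibble(
    time_s = as.double(time_s),
    systolic_mmhg = as.double(systolic_mmhg),
    diastolic_mmhg = as.double(diastolic_mmhg),
    map_mmhg = as.double(map_mmhg)
  )
  bad <- with(out, diastolic_mmhg > map_mmhg | map_mmhg > systolic_mmhg |
    diastolic_mmhg <= 0)
  if (any(bad)) {
    abort_linebp("invalid_parameter", sprintf(
      "%d cuff reading(s) violate diastolic <= MAP <= systolic (all positive).",
      sum(bad)
    ))
  }
  dplyr::arrange(out, .data$time_s)
}

#' Assemble one dialysis treatment session
#'
#' Bundles the two line-pressure traces, the cuff series and the hardware
#' configuration for a single treatment. Use [validate_session()] to check
#' the record's invariants without raising errors.
#'
#' @param arterial,venous [pressure_trace()] objects for the two lines.
#' @param cuffs A [cuff_measurements()] tibble.
#' @param arterial_needle,venous_needle [needle_spec()] objects.
#' @param pump A [pump_geometry()].
#' @param set_flow_ml_min Optional prescribed flow (ml/min), if known.
#' @param session_id Identifier string.
#' @param gauge_set Optional gauge-set label; defaults to the venous needle
#'   gauge (renal-unit sets are conventionally named after it).
#' @return A list of class `session_record`.
#' @export
session_record <- function(arterial, venous, cuffs,
                           arterial_needle = needle_spec(14),
                           venous_needle = needle_spec(14),
                           pump = pump_geometry(),
                           set_flow_ml_min = NULL,
                           session_id = "session-001",
                           gauge_set = NULL) {
  stopifnot(
    is_pressure_trace(arterial), is_pressure_trace(venous),
    inherits(arterial_needle, "needle_spec"),
    inherits(venous_needle, "needle_spec"),
    inherits(pump, "pump_geometry"),
    is.data.frame(cuffs)
  )
  if (is.null(gauge_set)) gauge_set <- as.character(venous_needle$gauge)
  structure(
    list(
      arterial = arterial, venous = venous, cuffs = cuffs,
      arterial_needle = arterial_needle, venous_needle = venous_needle,
      pump = pump, set_flow_ml_min = set_flow_ml_min,
      session_id = session_id, gauge_set = gauge_set
    ),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf(
    "<session_record> %s: %d cuff readings, gauges %sA/%sV, %g s of data @ %g Hz\n",
    x$session_id, nrow(x$cuffs),
    as.character(x$arterial_needle$gauge), as.character(x$venous_needle$gauge),
    nrow(x$arterial) / trace_sample_rate(x$arterial),
    trace_sample_rate(x$arterial)
  ))
  invisible(x)
}

finding <- function(severity, field, message) {
  tibble(severity = severity, field = field, message = message)
}

#' Validate a session record
#'
#' Checks the structural invariants of a [session_record()] and returns one
#' finding per violation rather than raising errors. Hard requirements
#' (matching sample rates, overlapping spans, cuff times inside the trace
#' span, ordered cuff pressures) are tagged `"error"`; the sign conventions of
#' the two channels (arterial predominantly negative under pump suction,
#' venous predominantly positive) are soft checks tagged `"warning"`.
#'
#' @param session A [session_record()].
#' @return A tibble with columns `severity`, `field`, `message`; zero rows
#'   for a well-formed session.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "session_record"))
  out <- finding(character(), character(), character())

  fa <- trace_sample_rate(session$arterial)
  fv <- trace_sample_rate(session$venous)
  if (!isTRUE(all.equal(fa, fv))) {
    out <- dplyr::bind_rows(out, finding(
      "error", "traces",
      sprintf("sample rates differ: arterial %g Hz, venous %g Hz.", fa, fv)
    ))
  }
  span_a <- c(trace_start_time(session$arterial), trace_end_time(session$arterial))
  span_v <- c(trace_start_time(session$venous), trace_end_time(session$venous))
  if (span_a[1] > span_v[2] || span_v[1] > span_a[2]) {
    out <- dplyr::bind_rows(out, finding(
      "error", "traces", "arterial and venous traces do not overlap in time."
    ))
  }
  span <- c(max(span_a[1], span_v[1]), min(span_a[2], span_v[2]))
  cuffs <- session$cuffs
  if (nrow(cuffs) > 0) {
    outside <- cuffs$time_s < span[1] - 1e-9 | cuffs$time_s > span[2] + 1e-9
    for (t in cuffs$time_s[outside]) {
      out <- dplyr::bind_rows(out, finding(
        "error", "cuffs",
        sprintf("cuff at t=%.1f s falls outside the trace span [%.1f, %.1f] s.",
                t, span[1], span[2])
      ))
    }
    bad <- cuffs$diastolic_mmhg > cuffs$map_mmhg |
      cuffs$map_mmhg > cuffs$systolic_mmhg | cuffs$diastolic_mmhg <= 0
    if (any(bad)) {
      out <- dplyr::bind_rows(out, finding(
        "error", "cuffs",
        sprintf("%d cuff reading(s) violate diastolic <= MAP <= systolic > 0.",
                sum(bad))
      ))
    }
  }
  # soft sign conventions: assessed over the second half of each trace, where
  # the pump is running in any record that includes a pump-off prefix
  half <- function(tr) tr$pressure_mmhg[seq(ceiling(nrow(tr) / 2), nrow(tr))]
  if (mean(half(session$arterial)) >= 0) {
    out <- dplyr::bind_rows(out, finding(
      "warning", "arterial",
      "arterial-line pressure is not predominantly negative during pumping."
    ))
  }
  if (mean(half(session$venous)) <= 0) {
    out <- dplyr::bind_rows(out, finding(
      "warning", "venous",
      "venous-line pressure is not predominantly positive during pumping."
    ))
  }
  for (side in c("arterial_needle", "venous_needle")) {
    ns <- session[[side]]
    if (abs(ns$area_mm2 - pi * (ns$inner_diameter_mm / 2)^2) > 1e-9) {
      out <- dplyr::bind_rows(out, finding(
        "error", side, "needle area inconsistent with inner diameter."
      ))
    }
  }
  out
}
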