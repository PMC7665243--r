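# Canonical internal units: pressure mmHg, flow ml/min, area mm^2, time s,
# frequency rad/s. The lumped parameter C is the one quantity whose natural
# units come from the Bernoulli relation itself (a density-like coefficient);
# see c_unit_scale().

.mmhg_to_pa <- 133.3224

#' Unit scale relating the lumped parameter C to canonical pressure/flow units
#'
#' The Bernoulli-derived relation between the brachial-arterial pressure gap
#' and line flow is `pb - p2 = 0.5 * (f / A2)^2 * C` when pressure is in Pa
#' and `f / A2` is a velocity in m/s, which makes `C` a density-like
#' coefficient in kg/m^3. `linebp` reports `C` in units of 10^3 kg/m^3
#' (numerically equal to g/cm^3), the scale on which clinically observed
#' values fall in the mid single digits to low tens. This function returns
#' the constant that converts the raw canonical-unit ratio
#' `2 * (pb - p2) / (flow / a2)^2` (mmHg over (ml/min/mm^2)^2) onto that
#' scale: `133.3224 * 3600 / 1000`.
#'
#' Passing `unit_scale = 1` to [c_from_point()] / [estimate_map()] gives the
#' raw canonical-unit ratio instead.
#'
#' @return A scalar conversion constant (approximately 479.96).
#' @seealso [c_from_point()], [estimate_map()]
#' @export
#' @examples
#' c_unit_scale()
c_unit_scale <- function() {
  .mmhg_to_pa * 3600 / 1000
}

# Default gauge -> inner diameter lookup (mm), standard dialysis-needle
# conventions. Overridable by passing inner_diameter_mm to needle_spec().
.gauge_id_table <- c(`14` = 1.60, `15` = 1.37, `16` = 1.19)

#' Default inner diameter for a dialysis needle gauge
#'
#' Returns the default inner diameter (mm) for the common dialysis needle
#' gauges 14, 15 and 16. Other gauges have no default and must be given an
#' explicit inner diameter in [needle_spec()].
#'
#' @param gauge Needle gauge (numeric or character).
#' @return Inner diameter in mm, or `NA` if the gauge has no default.
#' @export
#' @examples
#' gauge_inner_diameter(14)
gauge_inner_diameter <- function(gauge) {
  out <- .gauge_id_table[as.character(gauge)]
  unname(out)
}
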