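#' Search band for the pump fundamental frequency
#'
#' The peristaltic blood pump runs near 1 Hz at clinical flow rates, so the
#' default band is 0.2--3 Hz. `min_peak_snr` is the minimum ratio of the
#' in-band spectral peak to the median noise-floor power below which a window
#' is declared pump-off (or sensor fault); the noise floor is measured on a
#' sub-window-averaged spectrum over a reference band four times wider than
#' the search band, so genuine pump tones score orders of magnitude above
#' the default threshold of 5.
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low < high < fs/2`.
#' @param min_peak_snr Minimum peak-to-noise-floor power ratio.
#' @return A list of class `frequency_band`.
#' @export
frequency_band <- function(low_hz = 0.2, high_hz = 3.0, min_peak_snr = 5.0) {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) || low_hz <= 0 ||
      high_hz <= low_hz) {
    abort_linebp("invalid_parameter", "need 0 < low_hz < high_hz.")
  }
  if (!is.numeric(min_peak_snr) || min_peak_snr <= 0) {
    abort_linebp("invalid_parameter", "`min_peak_snr` must be positive.")
  }
  structure(
    list(low_hz = low_hz, high_hz = high_hz, min_peak_snr = min_peak_snr),
    class = "frequency_band"
  )
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# Welch-style averaged periodogram used only for pump-off detection:
# 4 half-overlapped Hann sub-windows tame the heavy tail of single-window
# noise periodograms so a fixed SNR threshold separates pump-on from
# pump-off reliably.
detection_snr <- function(x, fs, band) {
  n <- length(x)
  sl <- max(16L, floor(n / 2.5))
  hop <- max(1L, floor(sl / 2))
  starts <- seq(1L, n - sl + 1L, by = hop)
  w <- hann_window(sl)
  p <- rowSums(vapply(
    starts,
    function(s) Mod(fft(x[s:(s + sl - 1L)] * w))^2,
    numeric(sl)
  )) / length(starts)
  f <- (0:(sl - 1)) * fs / sl
  in_band <- f >= band$low_hz & f <= band$high_hz
  ref <- f >= band$low_hz & f <= min(4 * band$high_hz, fs / 2)
  if (!any(in_band)) {
    abort_linebp("invalid_parameter", "search band contains no spectral bins at this window length.")
  }
  max(p[in_band]) / median(p[ref])
}

#' Estimate the pump fundamental frequency from one window
#'
#' Locates the dominant spectral component within the search band of a
#' DC-removed, Hann-tapered, zero-padded periodogram and refines it to
#' sub-bin resolution by parabolic interpolation on the log-power of the
#' peak and its two neighbours. Windows with no in-band peak exceeding
#' `band$min_peak_snr` raise a `linebp_no_pump_signal` error, signalling a
#' stopped pump or a sensor fault.
#'
#' @param segment Numeric vector of pressure samples (one analysis window).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param band A [frequency_band()].
#' @return Angular frequency in rad/s, with attributes `peak_power` and
#'   `snr`.
#' @export
#' @examples
#' t <- (0:4999) / 1000
#' f <- fundamental_frequency(sin(2 * pi * 1.0 * t), 1000)
#' f / (2 * pi) # ~1 Hz
fundamental_frequency <- function(segment, sample_rate_hz,
                                  band = frequency_band()) {
  if (!is.numeric(segment) || anyNA(segment)) {
    abort_linebp("invalid_parameter", "`segment` must be numeric without missing values.")
  }
  fs <- sample_rate_hz
  if (band$high_hz >= fs / 2) {
    abort_linebp("invalid_parameter", "band high edge must be below the Nyquist frequency.")
  }
  n <- length(segment)
  if (n < fs / band$low_hz) {
    abort_linebp("invalid_parameter", sprintf(
      "segment must span at least one period of the band low edge (need %d samples, got %d).",
      ceiling(fs / band$low_hz), n
    ))
  }
  x <- segment - mean(segment)

  snr <- detection_snr(x, fs, band)
  if (snr < band$min_peak_snr) {
    abort_linebp("no_pump_signal", sprintf(
      "no in-band spectral peak above SNR %.1f (observed %.2f): pump off or sensor fault.",
      band$min_peak_snr, snr
    ))
  }

  w <- hann_window(n)
  nfft <- 2^(ceiling(log2(n)) + 3)
  p <- Mod(fft(c(x * w, numeric(nfft - n))))^2
  f <- (0:(nfft - 1)) * fs / nfft
  in_band <- which(f >= band$low_hz & f <= band$high_hz)
  k <- in_band[which.max(p[in_band])]

  delta <- 0
  if (k > 1 && k < nfft && all(p[(k - 1):(k + 1)] > 0)) {
    lp <- log(p[(k - 1):(k + 1)])
    denom <- lp[1] - 2 * lp[2] + lp[3]
    if (denom < 0) delta <- max(-0.5, min(0.5, 0.5 * (lp[1] - lp[3]) / denom))
  }
  freq_hz <- (k - 1 + delta) * fs / nfft
  structure(2 * pi * freq_hz, peak_power = p[k], snr = snr)
}

#' Convert pump frequency to blood flow
#'
#' One pump rotation displaces the volume of line swept by the rollers,
#' `pi * r^2 * Ln`, so flow is linear in rotation frequency:
#' `flow = (fr / 2 pi) * 60 * pi * r^2 * Ln` in mm^3/min, returned as
#' ml/min. When the detected spectral peak is the lobe-passing frequency
#' rather than the rotation frequency, set `detected_is_lobe_frequency` and
#' the frequency is first divided by the lobe count.
#'
#' @param frequency_rad_s Pump angular frequency, rad/s (>= 0).
#' @param pump A [pump_geometry()].
#' @param detected_is_lobe_frequency If `TRUE`, `frequency_rad_s` is the
#'   lobe-passing frequency (rotation x lobe count). Default `FALSE`.
#' @return Flow in ml/min.
#' @export
#' @examples
#' flow_from_frequency(2 * pi, pump_geometry(4, 107.8)) # ~325 ml/min
flow_from_frequency <- function(frequency_rad_s, pump = pump_geometry(),
                                detected_is_lobe_frequency = FALSE) {
  if (any(!is.finite(frequency_rad_s)) || any(frequency_rad_s < 0)) {
    abort_linebp("invalid_parameter", "`frequency_rad_s` must be finite and >= 0.")
  }
  rot <- if (isTRUE(detected_is_lobe_frequency)) {
    frequency_rad_s / pump$lobe_count
  } else {
    frequency_rad_s
  }
  vol_mm3 <- pi * pump$line_radius_mm^2 * pump$effective_length_mm
  (rot / (2 * pi)) * 60 * vol_mm3 / 1000
}

#' Continuous flow estimation over a session
#'
#' Runs [fundamental_frequency()] on every sliding window of the venous
#' trace and converts each frequency to flow. Windows in which no pump
#' signal is detected yield a gap (no row), not a zero.
#'
#' @param venous Venous-line [pressure_trace()].
#' @param pump A [pump_geometry()].
#' @param spec A [window_spec()].
#' @param band A [frequency_band()].
#' @param detected_is_lobe_frequency Passed to [flow_from_frequency()].
#' @return A tibble of class `flow_series`: one row per window with a
#'   detected pump tone, columns `time_s` (as-of time), `frequency_rad_s`,
#'   `flow_ml_min`, `window_width_samples`, `spectral_peak_power`, `snr`.
#' @export
flow_series <- function(venous, pump = pump_geometry(),
                        spec = window_spec(), band = frequency_band(),
                        detected_is_lobe_frequency = FALSE) {
  stopifnot(is_pressure_trace(venous))
  fs <- trace_sample_rate(venous)
  wins <- sliding_windows(venous, spec)
  rows <- purrr::map2(wins$segment, wins$time_s, function(seg, t) {
    fr <- tryCatch(
      fundamental_frequency(seg, fs, band),
      linebp_no_pump_signal = function(e) NULL
    )
    if (is.null(fr)) return(NULL)
    tibble(
      time_s = t,
      frequency_rad_s = as.double(fr),
      flow_ml_min = flow_from_frequency(as.double(fr), pump,
                                        detected_is_lobe_frequency),
      window_width_samples = spec$width_samples,
      spectral_peak_power = attr(fr, "peak_power"),
      snr = attr(fr, "snr")
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      time_s = double(), frequency_rad_s = double(), flow_ml_min = double(),
      window_width_samples = integer(), spectral_peak_power = double(),
      snr = double()
    )
  }
  structure(out, class = c("flow_series", class(out)))
}
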