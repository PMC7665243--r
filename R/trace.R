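#' Construct a uniformly sampled pressure trace
#'
#' A pressure trace is a tibble with columns `time_s` and `pressure_mmhg`
#' plus attributes recording the sample rate, the channel (arterial or
#' venous) and the start time. Time is seconds from session start; the first
#' sample sits at `start_time_s`.
#'
#' @param pressure_mmhg Numeric vector of pressure samples, mmHg.
#' @param sample_rate_hz Sampling rate in Hz (default 1000).
#' @param channel `"arterial"` or `"venous"`.
#' @param start_time_s Time of the first sample, seconds (default 0).
#' @return A tibble of class `pressure_trace`.
#' @export
#' @examples
#' tr <- pressure_trace(sin(2 * pi * (0:999) / 1000), 1000, "venous")
#' tr
pressure_trace <- function(pressure_mmhg,
                           sample_rate_hz = 1000,
                           channel = c("arterial", "venous"),
                           start_time_s = 0) {
  channel <- match.arg(channel)
  if (!is.numeric(pressure_mmhg) || length(pressure_mmhg) == 0) {
    abort_linebp("invalid_parameter", "`pressure_mmhg` must be a non-empty numeric vector.")
  }
  if (anyNA(pressure_mmhg)) {
    abort_linebp("invalid_parameter", "`pressure_mmhg` must not contain missing values.")
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 || sample_rate_hz <= 0) {
    abort_linebp("invalid_parameter", "`sample_rate_hz` must be a positive scalar.")
  }
  n <- length(pressure_mmhg)
  out <- tibble(
    time_s = start_time_s + (seq_len(n) - 1) / sample_rate_hz,
    pressure_mmhg = as.double(pressure_mmhg)
  )
  structure(out,
    sample_rate_hz = sample_rate_hz,
    channel = channel,
    start_time_s = start_time_s,
    class = c("pressure_trace", class(out))
  )
}

#' @rdname pressure_trace
#' @param x Object to test or query.
#' @export
is_pressure_trace <- function(x) inherits(x, "pressure_trace")

#' @rdname pressure_trace
#' @export
trace_sample_rate <- function(x) attr(x, "sample_rate_hz")

#' @rdname pressure_trace
#' @export
trace_channel <- function(x) attr(x, "channel")

#' @rdname pressure_trace
#' @export
trace_start_time <- function(x) attr(x, "start_time_s")

trace_end_time <- function(x) {
  trace_start_time(x) + (nrow(x) - 1) / trace_sample_rate(x)
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf(
    "<pressure_trace> channel=%s, %d samples @ %g Hz, span [%.3f, %.3f] s\n",
    trace_channel(x), nrow(x), trace_sample_rate(x),
    trace_start_time(x), trace_end_time(x)
  ))
  NextMethod()
}

# rebuild a trace with new values but same metadata
trace_update <- function(x, values) {
  pressure_trace(values,
    sample_rate_hz = trace_sample_rate(x),
    channel = trace_channel(x),
    start_time_s = trace_start_time(x)
  )
}

#' Causal moving-average filter for a pressure trace
#'
#' Applies a trailing (causal) boxcar mean of `width_samples` samples: output
#' sample `i` is the mean of input samples `max(1, i - width + 1) .. i`. The
#' shorter effective window at the start is a running mean over the samples
#' available so far, so no pressure values are fabricated and the output has
#' the same length, channel and sample rate as the input. The default
#' 5000-sample width at 1 kHz (5 s) suppresses the pump and cardiac
#' oscillations, leaving the quasi-steady-state line pressure used for
#' calibration.
#'
#' @param trace A [pressure_trace()].
#' @param width_samples Window width in samples; must be between 1 and the
#'   trace length.
#' @return A filtered [pressure_trace()].
#' @export
#' @examples
#' tr <- pressure_trace(0:9, 1, "arterial")
#' moving_average(tr, 3)$pressure_mmhg
moving_average <- function(trace, width_samples = 5000) {
  stopifnot(is_pressure_trace(trace))
  n <- nrow(trace)
  w <- width_samples
  if (!is.numeric(w) || length(w) != 1 || w < 1 || w != round(w)) {
    abort_linebp("invalid_parameter", "`width_samples` must be a positive integer.")
  }
  if (w > n) {
    abort_linebp("invalid_parameter", sprintf(
      "`width_samples` (%d) exceeds trace length (%d).", w, n
    ))
  }
  x <- trace$pressure_mmhg
  cs <- cumsum(x)
  out <- cs / seq_len(n)
  if (w < n) {
    i <- (w + 1):n
    out[i] <- (cs[i] - cs[i - w]) / w
    out[w] <- cs[w] / w
  }
  trace_update(trace, out)
}

#' Sliding-window specification
#'
#' Width and hop of the analysis window used for pump-frequency estimation
#' and MAP reconstruction. The default is a 5000-sample (5 s at 1 kHz) window
#' advanced by 1000 samples, i.e. estimates updated every second.
#'
#' @param width_samples Window width in samples (>= 2).
#' @param hop_samples Advance between windows in samples (1 <= hop <= width).
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(width_samples = 5000, hop_samples = 1000) {
  if (!is.numeric(width_samples) || width_samples < 2 ||
      width_samples != round(width_samples)) {
    abort_linebp("invalid_parameter", "`width_samples` must be an integer >= 2.")
  }
  if (!is.numeric(hop_samples) || hop_samples < 1 ||
      hop_samples != round(hop_samples) || hop_samples > width_samples) {
    abort_linebp("invalid_parameter", "`hop_samples` must be an integer in [1, width_samples].")
  }
  structure(
    list(width_samples = as.integer(width_samples),
         hop_samples = as.integer(hop_samples)),
    class = "window_spec"
  )
}

#' Extract sliding windows from a trace
#'
#' Segments of exactly `spec$width_samples` samples advancing by
#' `spec$hop_samples`; a final partial window is dropped. Each window carries
#' the time of its last sample, the "as-of" time of a real-time estimate.
#'
#' @param trace A [pressure_trace()].
#' @param spec A [window_spec()].
#' @return A tibble with columns `window_id`, `start_s`, `time_s` (as-of
#'   time) and list-column `segment`. Zero rows if the trace is shorter than
#'   one window.
#' @export
sliding_windows <- function(trace, spec = window_spec()) {
  stopifnot(is_pressure_trace(trace), inherits(spec, "window_spec"))
  n <- nrow(trace)
  w <- spec$width_samples
  if (n < w) {
    return(tibble(
      window_id = integer(), start_s = double(), time_s = double(),
      segment = list()
    ))
  }
  starts <- seq(1L, n - w + 1L, by = spec$hop_samples)
  x <- trace$pressure_mmhg
  t0 <- trace_start_time(trace)
  fs <- trace_sample_rate(trace)
  tibble(
    window_id = seq_along(starts),
    start_s = t0 + (starts - 1) / fs,
    time_s = t0 + (starts + w - 2) / fs,
    segment = purrr::map(starts, function(s) x[s:(s + w - 1L)])
  )
}

#' Pressure value nearest to a time point
#'
#' Returns the sample nearest to `t_s` (no interpolation); an exact midpoint
#' between two samples resolves to the earlier sample.
#'
#' @param trace A [pressure_trace()].
#' @param t_s Time(s) in seconds; must lie within the trace span.
#' @return Pressure in mmHg (vectorised over `t_s`).
#' @export
value_at_time <- function(trace, t_s) {
  stopifnot(is_pressure_trace(trace))
  fs <- trace_sample_rate(trace)
  t0 <- trace_start_time(trace)
  t1 <- trace_end_time(trace)
  if (any(t_s < t0 - 1e-9 | t_s > t1 + 1e-9)) {
    abort_linebp("out_of_range", sprintf(
      "time outside trace span [%.6f, %.6f] s.", t0, t1
    ))
  }
  k <- (t_s - t0) * fs
  idx <- pmax(1L, pmin(nrow(trace), as.integer(ceiling(k - 0.5 - 1e-9)) + 1L))
  trace$pressure_mmhg[idx]
}
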