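# Independent oracles used to cross-check the package's estimators.

# Brute-force dense-grid DFT argmax: windowed power evaluated directly at
# every frequency of a fine grid -- no FFT, no zero padding, no parabolic
# interpolation. The Hann taper is part of the spectral definition shared
# with the estimator; the peak *location* machinery being checked is
# entirely independent. Grid matrices are cached per segment length.
.oracle_cache <- new.env(parent = emptyenv())

oracle_dense_grid_peak <- function(x, fs, low_hz = 0.2, high_hz = 3.0,
                                   df = 0.002) {
  n <- length(x)
  x <- (x - mean(x)) * (0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)))
  key <- sprintf("n%d_fs%g_%g_%g_%g", n, fs, low_hz, high_hz, df)
  if (is.null(.oracle_cache[[key]])) {
    f <- seq(low_hz, high_hz, by = df)
    t <- (0:(n - 1)) / fs
    .oracle_cache[[key]] <- list(
      f = f,
      C = cos(2 * pi * outer(f, t)),
      S = sin(2 * pi * outer(f, t))
    )
  }
  g <- .oracle_cache[[key]]
  p <- (g$C %*% x)^2 + (g$S %*% x)^2
  g$f[which.max(p)]
}

# Closed-form simple linear regression via the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  sst <- sum((y - mean(y))^2)
  list(
    slope = slope, intercept = intercept,
    rmse = sqrt(mean(res^2)),
    r_squared = if (sst > 0) 1 - sum(res^2) / sst else 0
  )
}

# Shared pipeline shorthand: windowed flow plus moving-averaged arterial.
run_pipeline <- function(session, width = 5000, hop = 1000) {
  spec <- window_spec(width, hop)
  list(
    flow = flow_series(session$venous, session$pump, spec),
    filtered = moving_average(session$arterial, width),
    spec = spec
  )
}

# Fabricate a session_calibration for grouping-logic tests without running
# the full pipeline (the acceptance suite exercises the real path).
fake_calibration <- function(c_values, gauge, session_id,
                             flow = 325, a2 = needle_spec(14)$area_mm2) {
  n <- length(c_values)
  p2 <- seq(-180, -120, length.out = max(n, 2))[seq_len(n)]
  points <- tibble::tibble(
    time_s = seq(60, by = 60, length.out = n),
    pb_mmhg = estimate_map(c_values, p2, flow, a2),
    p2_mmhg = p2,
    flow_ml_min = flow,
    a2_mm2 = a2,
    c_value = c_values
  )
  structure(
    list(
      points = points,
      skipped = tibble::tibble(time_s = double(), reason = character()),
      c_session = mean(c_values),
      c_sd = if (n > 1) sd(c_values) else NA_real_,
      c_range = range(c_values),
      gauge_label = as.character(gauge),
      session_id = session_id,
      unit_scale = c_unit_scale()
    ),
    class = "session_calibration"
  )
}
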