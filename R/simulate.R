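#' Configuration for a simulated dialysis session
#'
#' Describes a synthetic treatment with known ground truth. The venous trace
#' is a positive baseline carrying the pump oscillation (fundamental plus a
#' second harmonic at `harmonic_ratio` of its amplitude) and sensor noise;
#' the arterial trace is generated from the inverted calibration relation,
#' `p2(t) = map(t) - 0.5 * (flow(t) / a2)^2 * c(t) / unit_scale`, plus pump
#' oscillation, a cardiac component and noise, so the calibration model is
#' exactly recoverable in the noiseless limit. Pump components are zero
#' before `pump_start_s`. Cuff readings sample the true MAP at regular
#' intervals with measurement noise; systolic/diastolic are synthesised as
#' MAP plus/minus plausible pulse-pressure offsets so that
#' diastolic <= MAP <= systolic always holds.
#'
#' The default is a 600 s test-scale session with 8 cuff readings, the
#' per-treatment cuff count of a 30-minute cadence over 4 hours;
#' [full_session_config()] gives the full-length profile (4 h, pump enabled
#' at 2000 s, cuffs every 30 min).
#'
#' The cardiac default of 1.2 Hz is deliberately non-harmonic with the ~1 Hz
#' pump tone at the default flow; configure `cardiac_freq_hz` equal to the
#' pump frequency to reproduce the known failure mode in which heart rate
#' and pump speed coincide.
#'
#' @param duration_s Session length, s.
#' @param sample_rate_hz Trace sampling rate, Hz.
#' @param flow_ml_min Set flow: a scalar, or a data frame
#'   `(time_s, flow_ml_min)` defining a piecewise-constant profile.
#' @param pump A [pump_geometry()].
#' @param pump_start_s Time at which the blood pump is enabled.
#' @param pump_amplitude_venous_mmhg,pump_amplitude_arterial_mmhg Amplitude
#'   of the pump oscillation on each line.
#' @param pump_tone_is_lobe If `TRUE`, the dominant venous tone is the
#'   lobe-passing frequency (rotation x lobes) instead of the rotation
#'   frequency; pair with `detected_is_lobe_frequency` in [flow_series()].
#' @param harmonic_ratio Second-harmonic amplitude relative to the
#'   fundamental.
#' @param cardiac_freq_hz,cardiac_amplitude_mmhg Cardiac component on the
#'   arterial line.
#' @param noise_sd_mmhg Additive white sensor noise on both lines.
#' @param true_c Session-mean lumped parameter (units of [c_unit_scale()]).
#' @param c_drift_total Total linear change of C over the session (centred
#'   on `true_c`).
#' @param c_noise_sd Slow C wobble: s.d. of piecewise-linear noise with
#'   60 s knots.
#' @param map_mmhg True MAP baseline.
#' @param map_drift_total Total linear MAP change over the session.
#' @param map_dips Optional data frame `(onset_s, duration_s, depth_mmhg)`
#'   of raised-cosine hypotensive dips.
#' @param venous_baseline_mmhg Venous pressure baseline while pumping.
#' @param venous_baseline_pre_pump_mmhg Venous baseline before pump start.
#' @param cuff_interval_s Interval between cuff readings.
#' @param cuff_first_s Time of the first cuff reading (default half the
#'   interval).
#' @param cuff_noise_sd_mmhg Cuff MAP measurement noise s.d.
#' @param pulse_pressure_mmhg,pulse_pressure_sd_mmhg Synthesised pulse
#'   pressure (systolic minus diastolic) mean and s.d.
#' @param arterial_gauge,venous_gauge Needle gauges.
#' @param gauge_set Optional gauge-set label (defaults to the venous gauge).
#' @param session_id Identifier.
#' @param seed RNG seed for this session.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 600,
                       sample_rate_hz = 1000,
                       flow_ml_min = 325,
                       pump = pump_geometry(),
                       pump_start_s = 0,
                       pump_amplitude_venous_mmhg = 30,
                       pump_amplitude_arterial_mmhg = 40,
                       pump_tone_is_lobe = FALSE,
                       harmonic_ratio = 0.3,
                       cardiac_freq_hz = 1.2,
                       cardiac_amplitude_mmhg = 5,
                       noise_sd_mmhg = 1,
                       true_c = 8,
                       c_drift_total = 0,
                       c_noise_sd = 0,
                       map_mmhg = 90,
                       map_drift_total = 0,
                       map_dips = NULL,
                       venous_baseline_mmhg = 150,
                       venous_baseline_pre_pump_mmhg = 10,
                       cuff_interval_s = 75,
                       cuff_first_s = NULL,
                       cuff_noise_sd_mmhg = 2,
                       pulse_pressure_mmhg = 40,
                       pulse_pressure_sd_mmhg = 5,
                       arterial_gauge = 14,
                       venous_gauge = 14,
                       gauge_set = NULL,
                       session_id = "sim-001",
                       seed = 1L) {
  if (duration_s <= 0 || sample_rate_hz <= 0) {
    abort_linebp("invalid_parameter", "`duration_s` and `sample_rate_hz` must be positive.")
  }
  flows <- if (is.data.frame(flow_ml_min)) flow_ml_min$flow_ml_min else flow_ml_min
  if (any(flows <= 0) || any(flows > 600)) {
    abort_linebp("invalid_parameter", "flow profile must lie in (0, 600] ml/min.")
  }
  amps <- c(pump_amplitude_venous_mmhg, pump_amplitude_arterial_mmhg,
            cardiac_amplitude_mmhg, noise_sd_mmhg, harmonic_ratio,
            cuff_noise_sd_mmhg, c_noise_sd)
  if (any(amps < 0)) {
    abort_linebp("invalid_parameter", "amplitudes and noise s.d. values must be >= 0.")
  }
  if (pump_start_s < 0 || pump_start_s > duration_s) {
    abort_linebp("invalid_parameter", "`pump_start_s` must lie within [0, duration_s].")
  }
  if (is.null(cuff_first_s)) cuff_first_s <- cuff_interval_s / 2
  cfg <- as.list(environment())
  cfg$flows <- NULL
  cfg$amps <- NULL
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param ... Overrides passed to [sim_config()].
#' @export
full_session_config <- function(...) {
  sim_config(
    duration_s = 14400, pump_start_s = 2000,
    cuff_interval_s = 1800, cuff_first_s = 900,
    ...
  )
}

# piecewise-constant flow profile as a function of time
flow_profile_fun <- function(flow_ml_min) {
  if (is.data.frame(flow_ml_min)) {
    stopifnot(all(c("time_s", "flow_ml_min") %in% names(flow_ml_min)))
    prof <- dplyr::arrange(flow_ml_min, .data$time_s)
    function(t) {
      idx <- findInterval(t, prof$time_s)
      out <- prof$flow_ml_min[pmax(idx, 1L)]
      out[idx < 1] <- prof$flow_ml_min[1]
      out
    }
  } else {
    function(t) rep(flow_ml_min, length(t))
  }
}

# slow piecewise-linear noise with knots every knot_s seconds
slow_noise <- function(t, sd, knot_s = 60) {
  if (sd <= 0) return(numeric(length(t)))
  kt <- seq(0, max(t) + knot_s, by = knot_s)
  kv <- rnorm(length(kt), 0, sd)
  approx(kt, kv, xout = t, rule = 2)$y
}

map_profile_values <- function(t, cfg) {
  dur <- cfg$duration_s
  m <- cfg$map_mmhg + cfg$map_drift_total * (t / dur - 0.5)
  if (!is.null(cfg$map_dips) && nrow(cfg$map_dips) > 0) {
    for (i in seq_len(nrow(cfg$map_dips))) {
      d <- cfg$map_dips[i, ]
      inside <- t >= d$onset_s & t <= d$onset_s + d$duration_s
      phase <- (t[inside] - d$onset_s) / d$duration_s
      m[inside] <- m[inside] - d$depth_mmhg * 0.5 * (1 - cos(2 * pi * phase))
    }
  }
  m
}

#' Simulate one dialysis session with ground truth
#'
#' Generates a [session_record()] from a [sim_config()] together with the
#' ground truth used to score every pipeline stage. The same seed yields a
#' bitwise-identical session; the global RNG state is left untouched.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_session` with elements `session` (a
#'   [session_record()]), `truth` (tibble at 1 s cadence: `time_s`,
#'   `flow_ml_min`, `c_true`, `map_mmhg`) and `config`.
#' @export
#' @examples
#' sim <- simulate_session(sim_config(duration_s = 60, seed = 42))
#' sim$session
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_session_impl(config))
}

simulate_session_impl <- function(cfg) {
  fs <- cfg$sample_rate_hz
  n <- round(cfg$duration_s * fs)
  t <- (0:(n - 1)) / fs
  a2 <- needle_spec(cfg$arterial_gauge)$area_mm2

  flow_fun <- flow_profile_fun(cfg$flow_ml_min)
  flow_t <- flow_fun(t)
  flow_t[t < cfg$pump_start_s] <- 0
  pump_on <- flow_t > 0

  # rotation frequency from the inverse of the frequency->flow relation
  vol_mm3 <- pi * cfg$pump$line_radius_mm^2 * cfg$pump$effective_length_mm
  rot_hz <- flow_t * 1000 / (60 * vol_mm3)
  tone_hz <- rot_hz * if (isTRUE(cfg$pump_tone_is_lobe)) cfg$pump$lobe_count else 1
  phase <- 2 * pi * cumsum(tone_hz) / fs

  ph <- runif(4, 0, 2 * pi)
  c_t <- cfg$true_c + cfg$c_drift_total * (t / cfg$duration_s - 0.5) +
    slow_noise(t, cfg$c_noise_sd)
  map_t <- map_profile_values(t, cfg)
  gap_t <- 0.5 * (flow_t / a2)^2 * c_t / c_unit_scale()

  venous_vals <- ifelse(pump_on, cfg$venous_baseline_mmhg,
                        cfg$venous_baseline_pre_pump_mmhg) +
    pump_on * (cfg$pump_amplitude_venous_mmhg * sin(phase + ph[1]) +
               cfg$harmonic_ratio * cfg$pump_amplitude_venous_mmhg *
                 sin(2 * phase + ph[2])) +
    rnorm(n, 0, cfg$noise_sd_mmhg)

  arterial_vals <- map_t - gap_t +
    pump_on * cfg$pump_amplitude_arterial_mmhg * sin(phase + ph[3]) +
    cfg$cardiac_amplitude_mmhg * sin(2 * pi * cfg$cardiac_freq_hz * t + ph[4]) +
    rnorm(n, 0, cfg$noise_sd_mmhg)

  cuff_times <- if (cfg$cuff_first_s <= cfg$duration_s - 1 / fs) {
    seq(cfg$cuff_first_s, cfg$duration_s - 1 / fs, by = cfg$cuff_interval_s)
  } else {
    numeric(0)
  }
  cuff_idx <- pmin(n, round(cuff_times * fs) + 1)
  cuff_map <- map_t[cuff_idx] + rnorm(length(cuff_times), 0, cfg$cuff_noise_sd_mmhg)
  pp <- pmax(10, cfg$pulse_pressure_mmhg +
               rnorm(length(cuff_times), 0, cfg$pulse_pressure_sd_mmhg))
  cuffs <- cuff_measurements(
    time_s = cuff_times,
    systolic_mmhg = cuff_map + 2 / 3 * pp,
    diastolic_mmhg = cuff_map - 1 / 3 * pp,
    map_mmhg = cuff_map
  )

  session <- session_record(
    arterial = pressure_trace(arterial_vals, fs, "arterial"),
    venous = pressure_trace(venous_vals, fs, "venous"),
    cuffs = cuffs,
    arterial_needle = needle_spec(cfg$arterial_gauge),
    venous_needle = needle_spec(cfg$venous_gauge),
    pump = cfg$pump,
    set_flow_ml_min = if (is.data.frame(cfg$flow_ml_min)) NULL else cfg$flow_ml_min,
    session_id = cfg$session_id,
    gauge_set = cfg$gauge_set
  )

  truth_idx <- seq(1L, n, by = fs)
  truth <- tibble(
    time_s = t[truth_idx],
    flow_ml_min = flow_t[truth_idx],
    c_true = c_t[truth_idx],
    map_mmhg = map_t[truth_idx]
  )
  structure(list(session = session, truth = truth, config = cfg),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %s (%g s, seed %d)\n",
              x$session$session_id, x$config$duration_s, x$config$seed))
  invisible(x)
}

#' Interpolate ground truth at arbitrary times
#'
#' Linear interpolation of the 1 s ground-truth grid of a [simulate_session()]
#' result. Exact for the constant and linear profiles used in most tests.
#'
#' @param sim A `sim_session`.
#' @param times Times in seconds.
#' @param what One of `"map_mmhg"`, `"c_true"`, `"flow_ml_min"`.
#' @return Numeric vector of ground-truth values.
#' @export
ground_truth_at <- function(sim, times, what = c("map_mmhg", "c_true", "flow_ml_min")) {
  what <- match.arg(what)
  approx(sim$truth$time_s, sim$truth[[what]], xout = times, rule = 2)$y
}

#' Simulate a cohort of dialysis sessions
#'
#' Mirrors a multi-patient feasibility study: sessions are assigned to
#' needle-gauge sets with gauge-dependent mean lumped parameters, plus
#' between-session and within-session C variation, per-session MAP levels
#' and drifts, and per-gauge clinical flow ranges (smaller needles run lower
#' flows). Gauge sets follow renal-unit convention: set 14 = 14g arterial /
#' 14g venous, set 15 = 15g/15g, set 16 = 15g arterial / 16g venous.
#' Per-session seeds are derived from the master seed.
#'
#' @param n_sessions Number of sessions (>= 1).
#' @param gauge_mix Named integer vector of session counts per gauge set;
#'   must sum to `n_sessions`.
#' @param gauge_mean_c Named vector of true mean C per gauge set.
#' @param between_session_c_sd S.d. of session mean C about the gauge mean.
#' @param within_session_c_sd S.d. over time of the within-session linear C
#'   drift.
#' @param map_range Range of per-session MAP baselines, mmHg.
#' @param map_drift_sd S.d. of the total within-session MAP drift.
#' @param duration_s,cuff_interval_s,noise_sd_mmhg Session-level settings
#'   passed to [sim_config()].
#' @param seed Master seed.
#' @param ... Further overrides passed to every [sim_config()].
#' @return A tibble with one row per session: `session_id`, `gauge_set`,
#'   `true_c_session`, `set_flow_ml_min` and list-column `sim` of
#'   `sim_session` objects.
#' @export
simulate_cohort <- function(n_sessions = 11,
                            gauge_mix = c(`14` = 6, `15` = 3, `16` = 2),
                            gauge_mean_c = c(`14` = 6, `15` = 8.5, `16` = 10.25),
                            between_session_c_sd = 0.5,
                            within_session_c_sd = 0.05,
                            map_range = c(70, 110),
                            map_drift_sd = 5,
                            duration_s = 600,
                            cuff_interval_s = 75,
                            noise_sd_mmhg = 1,
                            seed = 1L,
                            ...) {
  if (n_sessions < 1) {
    abort_linebp("invalid_parameter", "`n_sessions` must be >= 1.")
  }
  if (sum(gauge_mix) != n_sessions) {
    abort_linebp("invalid_parameter", "`gauge_mix` must sum to `n_sessions`.")
  }
  if (!all(names(gauge_mix) %in% names(gauge_mean_c))) {
    abort_linebp("invalid_parameter", "every gauge in `gauge_mix` needs a mean C in `gauge_mean_c`.")
  }
  needle_sets <- list(
    `14` = c(arterial = 14, venous = 14),
    `15` = c(arterial = 15, venous = 15),
    `16` = c(arterial = 15, venous = 16)
  )
  flow_ranges <- list(
    `14` = c(300, 394), `15` = c(280, 340), `16` = c(278, 310)
  )
  gauges <- rep(names(gauge_mix), times = gauge_mix)

  draws <- withr::with_seed(seed, {
    tibble(
      gauge_set = gauges,
      c_sess = gauge_mean_c[gauges] + rnorm(n_sessions, 0, between_session_c_sd),
      c_drift = sample(c(-1, 1), n_sessions, replace = TRUE) *
        2 * sqrt(3) * within_session_c_sd,
      flow = purrr::map_dbl(gauges, function(g) {
        r <- flow_ranges[[g]]
        if (is.null(r)) r <- c(278, 394)
        runif(1, r[1], r[2])
      }),
      map_base = runif(n_sessions, map_range[1], map_range[2]),
      map_drift = rnorm(n_sessions, 0, map_drift_sd * 2),
      sub_seed = sample.int(2^30, n_sessions)
    )
  })

  sims <- purrr::pmap(
    list(seq_len(n_sessions), draws$gauge_set, draws$c_sess, draws$c_drift,
         draws$flow, draws$map_base, draws$map_drift, draws$sub_seed),
    function(i, g, c_sess, c_drift, flow, map_base, map_drift, sub_seed) {
      ns <- needle_sets[[g]]
      if (is.null(ns)) ns <- c(arterial = as.numeric(g), venous = as.numeric(g))
      cfg <- sim_config(
        duration_s = duration_s,
        flow_ml_min = round(flow),
        true_c = c_sess,
        c_drift_total = c_drift,
        map_mmhg = map_base,
        map_drift_total = map_drift,
        noise_sd_mmhg = noise_sd_mmhg,
        cuff_interval_s = cuff_interval_s,
        arterial_gauge = ns[["arterial"]],
        venous_gauge = ns[["venous"]],
        gauge_set = g,
        session_id = sprintf("cohort-%02d", i),
        seed = sub_seed,
        ...
      )
      simulate_session(cfg)
    }
  )
  tibble(
    session_id = purrr::map_chr(sims, ~ .x$session$session_id),
    gauge_set = draws$gauge_set,
    true_c_session = draws$c_sess,
    set_flow_ml_min = round(draws$flow),
    sim = sims
  )
}
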