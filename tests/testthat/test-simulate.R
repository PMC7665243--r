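test_that("the same seed reproduces a session bitwise", {
  cfg <- sim_config(duration_s = 30, seed = 42)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$session$venous$pressure_mmhg, b$session$venous$pressure_mmhg)
  expect_identical(a$session$arterial$pressure_mmhg, b$session$arterial$pressure_mmhg)
  expect_identical(as.data.frame(a$session$cuffs), as.data.frame(b$session$cuffs))
  expect_identical(a$truth, b$truth)
})

test_that("simulation does not disturb the global RNG stream", {
  withr::with_seed(1, {
    r1 <- runif(1)
    invisible(simulate_session(sim_config(duration_s = 5, seed = 99)))
    r2 <- runif(1)
  })
  withr::with_seed(1, expected <- runif(2))
  expect_identical(c(r1, r2), expected)
})

test_that("pump disabled for the whole session yields no flow estimates", {
  cfg <- sim_config(duration_s = 60, pump_start_s = 60, seed = 8)
  sim <- simulate_session(cfg)
  fl <- flow_series(sim$session$venous, sim$session$pump)
  expect_equal(nrow(fl), 0)
})

test_that("synthesised cuff readings always satisfy diastolic <= MAP <= systolic", {
  for (seed in 1:8) {
    sim <- simulate_session(sim_config(duration_s = 120, cuff_interval_s = 15,
                                       cuff_first_s = 5, cuff_noise_sd_mmhg = 5,
                                       seed = seed))
    cuffs <- sim$session$cuffs
    expect_true(all(cuffs$diastolic_mmhg <= cuffs$map_mmhg))
    expect_true(all(cuffs$map_mmhg <= cuffs$systolic_mmhg))
  }
})

test_that("the venous tone can encode the lobe-passing frequency consistently", {
  cfg <- sim_config(duration_s = 60, pump_tone_is_lobe = TRUE, seed = 12)
  sim <- simulate_session(cfg)
  fl <- flow_series(sim$session$venous, sim$session$pump,
                    detected_is_lobe_frequency = TRUE)
  expect_lt(max(abs(fl$flow_ml_min - 325) / 325), 0.01)
  # misconfigured estimator reads double the flow
  fl_wrong <- flow_series(sim$session$venous, sim$session$pump)
  expect_gt(median(fl_wrong$flow_ml_min) / 325, 1.8)
})

test_that("noiseless generator and estimator are mutually consistent", {
  cfg <- sim_config(duration_s = 120, noise_sd_mmhg = 0, cuff_noise_sd_mmhg = 0,
                    cuff_interval_s = 30, cuff_first_s = 20, seed = 14)
  sim <- simulate_session(cfg)
  pipe <- run_pipeline(sim$session)
  expect_lt(max(abs(pipe$flow$flow_ml_min - 325) / 325), 0.005)
  cal <- session_calibration(sim$session, pipe$flow, pipe$filtered)
  expect_lt(abs(cal$c_session - 8) / 8, 0.01)
  est <- continuous_bp(sim$session, cal$c_session, pipe$flow, pipe$filtered)
  expect_lt(max(abs(est$map_mmhg - ground_truth_at(sim, est$time_s))), 1)
})

test_that("simulate_cohort assigns gauge sets, needles and derived seeds", {
  coh <- simulate_cohort(n_sessions = 11, duration_s = 10, seed = 3)
  expect_equal(nrow(coh), 11)
  expect_equal(as.integer(table(coh$gauge_set)[c("14", "15", "16")]),
               c(6L, 3L, 2L))
  s16 <- coh$sim[[which(coh$gauge_set == "16")[1]]]$session
  expect_equal(s16$arterial_needle$gauge, 15) # set 16 = 15g arterial / 16g venous
  expect_equal(s16$venous_needle$gauge, 16)
  # gauge-dependent flow prescription stays inside the study range
  expect_true(all(coh$set_flow_ml_min >= 278 & coh$set_flow_ml_min <= 394))
  # reproducible from the master seed
  coh2 <- simulate_cohort(n_sessions = 11, duration_s = 10, seed = 3)
  expect_identical(coh$sim[[5]]$session$venous$pressure_mmhg,
                   coh2$sim[[5]]$session$venous$pressure_mmhg)
  expect_error(simulate_cohort(n_sessions = 5, seed = 1),
               class = "linebp_invalid_parameter")
})

test_that("larger within-session C variation widens the pooled-vs-compensated R^2 gap", {
  gap_for <- function(within_sd) {
    coh <- simulate_cohort(
      n_sessions = 6, gauge_mix = c(`14` = 3, `15` = 2, `16` = 1),
      within_session_c_sd = within_sd, duration_s = 300,
      cuff_interval_s = 50, seed = 17
    )
    cals <- purrr::map(coh$sim, function(s) {
      pipe <- run_pipeline(s$session, hop = 5000)
      session_calibration(s$session, pipe$flow, pipe$filtered)
    })
    pair <- compensated_fit(cals)
    pair$compensated$r_squared - pair$pooled$r_squared
  }
  gaps <- purrr::map_dbl(c(0.05, 0.4, 1.2), gap_for)
  expect_true(all(diff(gaps) > 0))
})
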