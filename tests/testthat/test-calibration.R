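test_that("c_from_point implements the Bernoulli ratio", {
  # raw canonical-unit arithmetic: 2 * (100 - (-150)) / 50 = 10
  a2 <- 2
  flow <- a2 * sqrt(50)
  expect_equal(c_from_point(100, -150, flow, a2, unit_scale = 1), 10)
  expect_equal(c_from_point(-150, -150, 325, 2), 0) # pb = p2
  # default scale is the fixed unit conversion
  expect_equal(c_from_point(100, -150, flow, a2),
               10 * c_unit_scale())
  expect_error(c_from_point(100, -150, 0, 2), class = "linebp_invalid_parameter")
  expect_error(c_from_point(100, -150, 325, -1), class = "linebp_invalid_parameter")
})

test_that("c_from_point is scale-consistent in flow and area", {
  withr::with_seed(31, {
    pb <- runif(50, 60, 120)
    p2 <- runif(50, -250, -50)
    flow <- runif(50, 250, 400)
    a2 <- runif(50, 1, 3)
    k <- runif(50, 0.5, 4)
  })
  expect_equal(c_from_point(pb, p2, flow * k, a2 * k),
               c_from_point(pb, p2, flow, a2), tolerance = 1e-12)
})

test_that("estimate_map is the exact algebraic inverse of c_from_point", {
  withr::with_seed(32, {
    pb <- runif(200, 50, 130)
    p2 <- runif(200, -300, -20)
    flow <- runif(200, 100, 500)
    a2 <- runif(200, 0.8, 3)
  })
  cc <- c_from_point(pb, p2, flow, a2)
  expect_equal(estimate_map(cc, p2, flow, a2), pb, tolerance = 1e-12)
})

test_that("session_calibration recovers a constant C on a noiseless session", {
  cfg <- sim_config(duration_s = 300, true_c = 8, noise_sd_mmhg = 0,
                    cuff_noise_sd_mmhg = 0, cuff_interval_s = 60,
                    cuff_first_s = 30, seed = 41)
  sim <- simulate_session(cfg)
  pipe <- run_pipeline(sim$session)
  cal <- session_calibration(sim$session, pipe$flow, pipe$filtered)
  expect_equal(nrow(cal$points), 5)
  expect_lt(abs(cal$c_session - 8) / 8, 0.02)
  expect_lt(max(abs(cal$points$c_value - 8) / 8), 0.01)
  expect_equal(nrow(cal$skipped), 0)
})

test_that("cuffs before pump start are skipped; none usable raises no-calibration", {
  cfg <- sim_config(duration_s = 120, pump_start_s = 120, cuff_interval_s = 30,
                    cuff_first_s = 15, seed = 42)
  sim <- simulate_session(cfg)
  pipe <- run_pipeline(sim$session)
  expect_equal(nrow(pipe$flow), 0)
  expect_error(session_calibration(sim$session, pipe$flow, pipe$filtered),
               class = "linebp_no_calibration")
})

test_that("a linear C drift yields monotone per-point C and the mid value as session C", {
  cfg <- sim_config(duration_s = 300, true_c = 7, c_drift_total = 2,
                    noise_sd_mmhg = 0, cuff_noise_sd_mmhg = 0,
                    cuff_interval_s = 50, cuff_first_s = 25, seed = 43)
  sim <- simulate_session(cfg)
  pipe <- run_pipeline(sim$session)
  cal <- session_calibration(sim$session, pipe$flow, pipe$filtered)
  expect_true(all(diff(cal$points$c_value) > 0))
  expect_lt(abs(cal$c_session - 7) / 7, 0.02)
})

test_that("median aggregation is available behind a flag", {
  sim <- simulate_session(sim_config(duration_s = 120, cuff_interval_s = 30,
                                     cuff_first_s = 20, seed = 44))
  pipe <- run_pipeline(sim$session)
  m1 <- session_calibration(sim$session, pipe$flow, pipe$filtered)
  m2 <- session_calibration(sim$session, pipe$flow, pipe$filtered,
                            aggregate = "median")
  expect_equal(m1$c_session, mean(m1$points$c_value))
  expect_equal(m2$c_session, median(m1$points$c_value))
})

test_that("group_c_by_gauge recovers gauge-dependent core means and orders groups", {
  withr::with_seed(51, {
    cals <- c(
      purrr::map(1:3, ~ fake_calibration(rnorm(8, 6, 0.3), 14, paste0("g14-", .x))),
      purrr::map(1:3, ~ fake_calibration(rnorm(8, 8.5, 0.3), 15, paste0("g15-", .x))),
      purrr::map(1:3, ~ fake_calibration(rnorm(8, 10.25, 0.3), 16, paste0("g16-", .x)))
    )
  })
  gs <- group_c_by_gauge(cals)
  expect_equal(gs$gauge, c("14", "15", "16"))
  expect_lt(abs(gs$c_core_mean[1] - 6) / 6, 0.05)
  expect_lt(abs(gs$c_core_mean[2] - 8.5) / 8.5, 0.05)
  expect_lt(abs(gs$c_core_mean[3] - 10.25) / 10.25, 0.05)
  expect_true(all(diff(gs$c_core_mean) > 0))
})

test_that("a single clean gauge group has no outliers; a shifted session is flagged", {
  withr::with_seed(52, {
    clean <- purrr::map(1:4, ~ fake_calibration(rnorm(8, 6, 0.25), 14,
                                                paste0("ok-", .x)))
    shifted <- fake_calibration(rnorm(8, 10, 0.25), 14, "outlier")
  })
  gs_clean <- group_c_by_gauge(clean)
  expect_equal(nrow(gs_clean), 1)
  expect_equal(gs_clean$n_outliers, 0)

  gs <- group_c_by_gauge(c(clean, list(shifted)))
  pts <- gs$points[[1]]
  expect_true(all(pts$is_outlier[pts$session_id == "outlier"]))
  expect_false(any(pts$is_outlier[pts$session_id != "outlier"]))
})

test_that("a session with inflated C noise surfaces as outlier points", {
  withr::with_seed(53, {
    clean <- purrr::map(1:5, ~ fake_calibration(rnorm(8, 6, 0.25), 14,
                                                paste0("ok-", .x)))
    noisy <- fake_calibration(rnorm(8, 6, 3 * 0.25 * 3), 14, "noisy")
  })
  gs <- group_c_by_gauge(c(clean, list(noisy)))
  pts <- gs$points[[1]]
  flagged <- pts$session_id[pts$is_outlier]
  expect_gt(sum(flagged == "noisy"), 0)
  expect_true(all(flagged == "noisy"))
})
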