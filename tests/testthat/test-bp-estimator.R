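test_that("estimate_map degenerates to the line pressure at C = 0", {
  expect_equal(estimate_map(0, -150, 325, 2), -150)
  expect_error(estimate_map(8, -150, -1, 2), class = "linebp_invalid_parameter")
  expect_error(estimate_map(8, -150, 325, 0), class = "linebp_invalid_parameter")
})

test_that("continuous MAP on a noiseless constant-C session stays within 1 mmHg of truth", {
  cfg <- sim_config(duration_s = 180, noise_sd_mmhg = 0,
                    cuff_noise_sd_mmhg = 0, cuff_interval_s = 40,
                    cuff_first_s = 20, seed = 61)
  sim <- simulate_session(cfg)
  pipe <- run_pipeline(sim$session)
  cal <- session_calibration(sim$session, pipe$flow, pipe$filtered)
  est <- continuous_bp(sim$session, cal$c_session, pipe$flow, pipe$filtered)
  err <- est$map_mmhg - ground_truth_at(sim, est$time_s)
  expect_lt(max(abs(err)), 1)
})

test_that("a hypotensive dip appears in the estimate with correct depth and timing", {
  dips <- tibble::tibble(onset_s = 300, duration_s = 300, depth_mmhg = 25)
  cfg <- sim_config(duration_s = 900, map_dips = dips, cuff_interval_s = 120,
                    cuff_first_s = 60, seed = 62)
  sim <- simulate_session(cfg)
  pipe <- run_pipeline(sim$session)
  cal <- session_calibration(sim$session, pipe$flow, pipe$filtered)
  est <- continuous_bp(sim$session, cal$c_session, pipe$flow, pipe$filtered)
  t_min <- est$time_s[which.min(est$map_mmhg)]
  expect_lt(abs(t_min - 450), 10) # dip nadir at the profile centre
  depth <- max(est$map_mmhg[est$time_s < 250]) - min(est$map_mmhg)
  expect_lt(abs(depth - 25), 3)
})

test_that("pump-off prefix leaves the MAP estimate without early samples", {
  cfg <- sim_config(duration_s = 150, pump_start_s = 60, cuff_interval_s = 30,
                    cuff_first_s = 75, seed = 63)
  sim <- simulate_session(cfg)
  pipe <- run_pipeline(sim$session)
  cal <- session_calibration(sim$session, pipe$flow, pipe$filtered)
  est <- continuous_bp(sim$session, cal$c_session, pipe$flow, pipe$filtered)
  expect_false(any(est$time_s < 60))
  expect_error(
    continuous_bp(sim$session, cal$c_session, pipe$flow[0, ], pipe$filtered),
    class = "linebp_no_estimate"
  )
})

test_that("MAP estimate is insensitive to 2 mmHg arterial sensor noise after averaging", {
  cfg <- sim_config(duration_s = 120, noise_sd_mmhg = 0,
                    cuff_noise_sd_mmhg = 0, cuff_interval_s = 30,
                    cuff_first_s = 20, seed = 64)
  sim <- simulate_session(cfg)
  pipe <- run_pipeline(sim$session)
  withr::with_seed(99, noise <- rnorm(nrow(sim$session$arterial), 0, 2))
  noisy <- pressure_trace(sim$session$arterial$pressure_mmhg + noise,
                          1000, "arterial")
  filt_noisy <- moving_average(noisy, 5000)
  e1 <- continuous_bp(sim$session, 8, pipe$flow, pipe$filtered)
  e2 <- continuous_bp(sim$session, 8, pipe$flow, filt_noisy)
  expect_lt(max(abs(e2$map_mmhg - e1$map_mmhg)), 0.5)
})

test_that("the causal C policy uses only cuff points seen so far", {
  cfg <- sim_config(duration_s = 240, cuff_interval_s = 60, cuff_first_s = 60,
                    seed = 65)
  sim <- simulate_session(cfg)
  pipe <- run_pipeline(sim$session)
  cal <- session_calibration(sim$session, pipe$flow, pipe$filtered)
  est <- continuous_bp(sim$session, flow = pipe$flow,
                       filtered_arterial = pipe$filtered,
                       c_policy = "causal", calibration = cal)
  expect_false(any(est$time_s < cal$points$time_s[1])) # no C before 1st cuff
  first_window <- est$c_value[est$time_s < cal$points$time_s[2]]
  expect_true(all(first_window == cal$points$c_value[1]))
  late <- est$c_value[est$time_s >= max(cal$points$time_s)]
  expect_true(all(abs(late - cal$c_session) < 1e-12))
})

test_that("fit_map_vs_arterial reproduces exact linear data and matches the OLS oracle", {
  p2 <- seq(-200, -60, length.out = 12)
  exact <- tibble::tibble(p2_mmhg = p2, pb_mmhg = 0.8 * p2 - 150)
  fit <- fit_map_vs_arterial(exact)
  expect_equal(fit$slope, 0.8, tolerance = 1e-10)
  expect_equal(fit$intercept, -150, tolerance = 1e-8)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)

  withr::with_seed(71, {
    pts <- tibble::tibble(
      p2_mmhg = runif(40, -250, -50),
      pb_mmhg = 70 + 0.5 * runif(40, -250, -50) + rnorm(40, 0, 8)
    )
  })
  fit2 <- fit_map_vs_arterial(pts)
  orc <- oracle_ols(pts$p2_mmhg, pts$pb_mmhg)
  expect_equal(fit2$slope, orc$slope, tolerance = 1e-10)
  expect_equal(fit2$intercept, orc$intercept, tolerance = 1e-10)
  expect_equal(fit2$rmse, orc$rmse, tolerance = 1e-10)
  expect_equal(fit2$r_squared, orc$r_squared, tolerance = 1e-10)
})

test_that("degenerate fits are rejected; constant response gives slope 0, R^2 0", {
  expect_error(fit_map_vs_arterial(tibble::tibble(p2_mmhg = 1:2, pb_mmhg = 1:2)),
               class = "linebp_degenerate_fit")
  expect_error(
    fit_map_vs_arterial(tibble::tibble(p2_mmhg = rep(-100, 5), pb_mmhg = 1:5)),
    class = "linebp_degenerate_fit"
  )
  flat <- fit_map_vs_arterial(tibble::tibble(p2_mmhg = c(-1, -2, -3, -4) * 50,
                                             pb_mmhg = rep(90, 4)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)
})

test_that("tidy and glance methods expose the fit in broom style", {
  p2 <- seq(-200, -60, length.out = 10)
  withr::with_seed(72, pb <- 0.8 * p2 - 150 + rnorm(10))
  fit <- fit_map_vs_arterial(tibble::tibble(p2_mmhg = p2, pb_mmhg = pb))
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "p2_mmhg"))
  gl <- glance(fit)
  expect_true(all(c("slope", "rmse", "r.squared", "nobs") %in% names(gl)))
  expect_equal(gl$nobs, 10)
})

test_that("compensation collapses to identity for one shared constant C", {
  cals <- purrr::map(1:3, function(i) {
    fake_calibration(rep(7.5, 4), 14, paste0("s", i), flow = 300 + 20 * i)
  })
  pair <- compensated_fit(cals)
  expect_equal(pair$pooled$slope, pair$compensated$slope, tolerance = 1e-9)
  expect_equal(pair$pooled$r_squared, pair$compensated$r_squared,
               tolerance = 1e-9)
})

test_that("compensated_fit enforces its preconditions", {
  one <- list(fake_calibration(c(7, 8, 7.5), 14, "only"))
  expect_error(compensated_fit(one), class = "linebp_invalid_parameter")
  thin <- list(fake_calibration(c(7, 8), 14, "a"),
               fake_calibration(8, 14, "b"))
  expect_error(compensated_fit(thin), class = "linebp_invalid_parameter")
})
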