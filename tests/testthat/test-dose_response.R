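test_that("normalization divides by OD and subtracts the time-zero value", {
  times <- c(0, 20, 40)
  # signal = 7 * od600 at all times: normalized signal is constant, so the
  # background-subtracted value is zero everywhere
  ts <- manual_plate(times, c(0, 50), function(d, t) 7, od = 1)
  ts$od600 <- rep(c(1, 2, 4), 2)
  ts$signal <- 7 * ts$od600
  norm <- normalize_and_background(ts)
  expect_equal(norm$signal, rep(0, 6))
  # already-normalized input with zero baseline passes through unchanged
  ts2 <- manual_plate(times, c(0, 50), function(d, t) d * t)
  norm2 <- normalize_and_background(ts2, use_od = FALSE)
  expect_equal(norm2$signal, ts2$signal)
  # 3-well hand-worked table
  ts3 <- tibble::tibble(
    time_min = rep(c(0, 20), 3),
    well = rep(c("w1", "w2", "w3"), each = 2),
    dnt_ug_per_l = rep(c(0, 10, 20), each = 2),
    od600 = c(0.1, 0.2, 0.1, 0.4, 0.2, 0.5),
    signal = c(5, 30, 5, 80, 12, 150),
    replicate = 1L
  )
  norm3 <- normalize_and_background(ts3)
  expect_equal(norm3$signal,
               c(0, 30 / 0.2 - 50, 0, 80 / 0.4 - 50, 0, 150 / 0.5 - 60))
  expect_error(normalize_and_background(ts3[ts3$time_min > 0, ]),
               "time-zero")
})

test_that("induction ratios divide sample by control", {
  times <- 0:4 * 20
  ts <- manual_plate(times, c(0, 10, 20), function(d, t) {
    (1 + d / 10) * t  # sample = (1 + d/10) x control
  })
  expect_equal(induction_ratio(ts, 10, 40), 2)
  expect_equal(induction_ratio(ts, 0, 40), 1)
  expect_error(induction_ratio(ts, 10, 40.5), "not measured")
  expect_error(induction_ratio(ts, 10, 0), "not positive")
  # replicates are averaged before the ratio
  ts2 <- rbind(ts, ts)
  ts2$replicate <- rep(1:2, each = nrow(ts))
  ts2$signal[seq_len(nrow(ts))] <- ts2$signal[seq_len(nrow(ts))] * 0.5
  ts2$signal[-seq_len(nrow(ts))] <- ts2$signal[-seq_len(nrow(ts))] * 1.5
  expect_equal(induction_ratio(tibble::as_tibble(ts2), 10, 40), 2)
})

test_that("max delta RLU is the windowed maximum difference", {
  times <- c(0, 60, 120, 180)
  same <- manual_plate(times, c(0, 10), function(d, t) t)
  expect_equal(max_delta_rlu(same, 10), 0)
  plus5 <- manual_plate(times, c(0, 10), function(d, t) t + 5 * (d > 0))
  expect_equal(max_delta_rlu(plus5, 10), 5)
  # hand-worked 4-timepoint series: differences 0, 10, 40, 25
  hand <- manual_plate(times, c(0, 10), function(d, t) {
    if (d == 0) t else t + c(0, 10, 40, 25)[match(t, times)]
  })
  expect_equal(max_delta_rlu(hand, 10, window_min = 360), 40)
  expect_equal(max_delta_rlu(hand, 10, window_min = 70), 10)
  expect_error(max_delta_rlu(hand, 10, window_min = -1), "window")
})

test_that("EC200 interpolates log-linearly and flags exact hits", {
  expect_equal(ec200(c("10" = 1.5, "100" = 2.0)), 100)
  expect_equal(ec200(c("10" = 1.5, "100" = 3.0)),
               10^(1 + (2 - 1.5) / (3 - 1.5)))
  # smallest crossing wins on non-monotone curves
  expect_equal(ec200(c("1" = 1, "10" = 3, "100" = 1.5, "1000" = 4)),
               10^(0 + 0.5))
  expect_warning(out <- ec200(c("10" = 1.2, "100" = 1.8)),
                 class = "sortscreen_undefined")
  expect_true(is.na(out))
  # invariant to rescaling the underlying signals: ratios unchanged
  r <- c("10" = 1.5, "100" = 3.0)
  expect_equal(ec200(r), ec200(r * 1))
  expect_error(ec200(c(1.5, 3)), "names")
})

test_that("EC200 recovery from simulated curves is within 5%", {
  ph <- variant_phenotype(induction_fold = 5, half_max_dnt = 10,
                          hill_coeff = 1.5, noise_sd_log = 0)
  concs_mg <- 10^seq(-1, 2, by = 1 / 8)  # 8 points per decade
  ts <- simulate_plate_timeseries(ph, concs_mg, duration_min = 360,
                                  interval_min = 20, seed = 1,
                                  n_replicates = 1)
  m <- compute_dose_response(ts, window_min = 360)
  # analytic ratio-2 crossing of the simulated kinetics at the window end
  # (induced component delayed by 40 min, time constants 240 and 120 min)
  g <- (1 - exp(-(360 - 40) / 240)) / (1 - exp(-360 / 120))
  x <- 1 / ((ph$induction_fold - 1) * g)
  analytic_ug <- 1000 * ph$half_max_dnt * (x / (1 - x))^(1 / ph$hill_coeff)
  expect_lt(abs(m$ec200 - analytic_ug) / analytic_ug, 0.05)
})

test_that("time to ratio interpolates the first crossing", {
  times <- c(0, 60, 75, 90)
  ts <- manual_plate(times, c(0, 10), function(d, t) {
    if (d == 0) t else t * c(1, 1.8, 2.2, 2.5)[match(t, times)]
  })
  expect_equal(time_to_ratio(ts, 10), 60 + (2 - 1.8) / (2.2 - 1.8) * 15)
  ts_exact <- manual_plate(times, c(0, 10), function(d, t) {
    if (d == 0) t else t * c(1, 1.5, 2, 3)[match(t, times)]
  })
  expect_equal(time_to_ratio(ts_exact, 10), 75)
  ts_never <- manual_plate(times, c(0, 10), function(d, t) t * 1.1)
  expect_warning(out <- time_to_ratio(ts_never, 10),
                 class = "sortscreen_undefined")
  expect_true(is.na(out))
})

test_that("response time shortens as induction strengthens", {
  t2 <- vapply(c(3, 10, 40), function(f) {
    ph <- variant_phenotype(induction_fold = f, half_max_dnt = 1,
                            noise_sd_log = 0)
    ts <- simulate_plate_timeseries(ph, 10, duration_min = 720,
                                    interval_min = 20, seed = 2,
                                    n_replicates = 1)
    time_to_ratio(normalize_and_background(ts), 10000)
  }, numeric(1))
  expect_true(all(diff(t2) <= 0))
  expect_lt(t2[3], t2[1])
})

test_that("fold metrics compare strains and invert on swap", {
  ref <- dose_response_metrics(70, 37000, 118)
  var <- dose_response_metrics(10, 1707000, 72)
  fm <- fold_metrics(ref, var)
  expect_equal(fm$threshold_fold, 7)
  expect_equal(fm$signal_fold, 1707000 / 37000)
  expect_equal(fm$response_time_reduction_pct, 100 * (118 - 72) / 118)
  same <- fold_metrics(ref, ref)
  expect_equal(same$threshold_fold, 1)
  expect_equal(same$signal_fold, 1)
  expect_equal(same$response_time_reduction_pct, 0)
  swapped <- fold_metrics(var, ref)
  expect_equal(swapped$threshold_fold, 1 / fm$threshold_fold)
  expect_equal(swapped$signal_fold, 1 / fm$signal_fold)
  # undefined inputs propagate
  na_m <- dose_response_metrics(NA_real_, NA_real_, NA_real_)
  expect_true(all(is.na(unlist(fold_metrics(ref, na_m)))))
})
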