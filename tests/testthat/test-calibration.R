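# Observation-window calibration.

test_that("band extraction returns filtered real-part rows of the scalogram", {
  est <- split_and_refine(prior_energy_spectrum(), tau = 0)
  scal <- cwt_morlet(numeric(300), 1:241)
  scal$fs <- FS
  b <- extract_bands(scal, est, fs = FS)
  expect_equal(b$x_e, numeric(300))
  expect_equal(b$x_c, numeric(300))

  bad <- est
  bad$mu_e_hat <- 999L
  expect_error(extract_bands(scal, bad, fs = FS), "not on the scalogram grid")
})

test_that("the event band of a sinusoid oscillates at the signal frequency", {
  n <- round(10 * FS)
  tt <- (0:(n - 1)) / FS
  x <- sin(2 * pi * 1.6 * tt)
  scal <- cwt_morlet(x, 1:241)
  scal$fs <- FS
  s_peak <- which.max(energy_spectrum(scal))
  est <- structure(list(tau = 0L, s_lambda = 120L,
                        mu_e_hat = as.integer(s_peak), mu_c_hat = 150L),
                   class = "scale_estimate")
  b <- extract_bands(scal, est, fs = FS)
  spec <- Mod(stats::fft(b$x_e))[1:(n %/% 2)]
  f_grid <- (seq_len(n %/% 2) - 1) * FS / n
  f_dom <- f_grid[which.max(spec)]
  expect_lt(abs(f_dom - 1.6), FS / n + 1e-9) # within one FFT bin
})

test_that("the 10 Hz band filter passes a 1 Hz component almost unchanged", {
  n <- round(10 * FS)
  tt <- (0:(n - 1)) / FS
  bf <- signal::butter(2, 10 / (FS / 2), type = "low")
  y <- signal::filtfilt(bf, sin(2 * pi * 1 * tt))
  mid <- y[(n %/% 4):(3 * n %/% 4)]
  expect_equal(max(abs(mid)), 1, tolerance = 0.02)
})

test_that("negative peaks of the event band segment the window", {
  T_ <- 50
  x <- -cos(2 * pi * (0:174) / T_) # 3.5 periods, minima at 0, 50, 100, 150
  regions <- segment_regions(x)
  expect_length(regions, 4) # 3 interior minima -> 4 regions
  expect_equal(vapply(regions, `[`, numeric(1), 1), c(1, 51, 101, 151))
  expect_equal(vapply(regions, `[`, numeric(1), 2), c(51, 101, 151, 175))

  x2 <- rep(1, 300)
  x2[149:151] <- c(0.5, -1, 0.5)
  regions2 <- segment_regions(x2)
  expect_equal(regions2, list(c(1, 150), c(150, 300)))

  expect_error(segment_regions(abs(sin(1:100))), "no negative peak")
})

test_that("window events on a noiseless trial alternate and track the bursts", {
  trial <- cached_trial("level", seed = 21, noise = 0)
  pre <- preprocess_trace(trial$accel)
  cal <- calibrate_gait(pre$jerk, pre$onset$n_start)
  ev <- cal$events
  expect_gte(nrow(ev), 3)
  expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)])) # alternating
  expect_true(all(diff(ev$t) > 0))
  # each window event lies a short, consistent lag after one true burst
  truth <- trial$truth
  lag <- vapply(ev$t, function(t0) t0 - truth$t[which.min(abs(truth$t - t0))],
                numeric(1))
  kind_truth <- vapply(ev$t, function(t0) {
    truth$kind[which.min(abs(truth$t - t0))]
  }, character(1))
  expect_true(all(lag > 0 & lag < 0.3))
  expect_identical(ev$kind, kind_truth)
})

test_that("argmax tie inside a region breaks to the smallest index", {
  J <- rep(2, 300) # constant: every region's peak is its first sample
  T_ <- 60
  x_e <- -cos(2 * pi * (0:299) / T_)
  x_c <- sin(2 * pi * (0:299) / (2 * T_))
  ev <- detect_window_events(J, list(x_e = x_e, x_c = x_c), fs = FS)
  starts <- vapply(segment_regions(x_e), `[`, numeric(1), 1)
  expect_true(all(ev$n %in% starts))
})

test_that("threshold arithmetic follows the window-event definitions", {
  ev <- data.frame(kind = c("HS", "TO", "HS"), n = c(75, 178, 252),
                   t = c(0.5, 1.2, 1.7), amplitude = c(4, 2, 4.4),
                   stringsAsFactors = FALSE)
  th <- compute_thresholds(ev, J_win = c(1, 2, 3, 4, 100))
  expect_equal(th$TH2, 3) # median is robust to the outlier
  expect_equal(th$TH3, 4.2)
  expect_equal(th$TH4, 2)
  expect_equal(th$T_swin, 0.5)
  expect_equal(th$T_std, 0.7)

  only_hs <- ev[ev$kind == "HS", ]
  expect_error(compute_thresholds(only_hs, 1:10), "no TO event")
  expect_error(compute_thresholds(ev[1:2, ], 1:10), "no TO->HS")
})

test_that("calibration recovers the programmed swing time within 10%", {
  swings <- vapply(1:20, function(s) {
    trial <- cached_trial("level", seed = 100 + s)
    pre <- preprocess_trace(trial$accel)
    cal <- calibrate_gait(pre$jerk, pre$onset$n_start)
    cal$thresholds$T_swin
  }, numeric(1))
  programmed <- terrain_presets()$level$swing_frac / terrain_presets()$level$cadence
  expect_equal(mean(swings), programmed, tolerance = 0.1)
})

test_that("thresholds are invariant to a constant acceleration offset", {
  trial <- cached_trial("level", seed = 22, noise = 0)
  tr <- trial$accel
  tr_off <- accel_trace(tr$ax + 0.37, tr$ay - 0.21, tr$az + 0.11, fs = tr$fs)
  pre1 <- preprocess_trace(tr)
  pre2 <- preprocess_trace(tr_off)
  n0 <- pre1$onset$n_start # fix the window so only the offset differs
  cal1 <- calibrate_gait(pre1$jerk, n0)
  cal2 <- calibrate_gait(pre2$jerk, n0)
  expect_equal(coef(cal1), coef(cal2), tolerance = 1e-3)
})

test_that("scaling the acceleration scales amplitudes but not durations", {
  trial <- cached_trial("level", seed = 22, noise = 0)
  tr <- trial$accel
  c_ <- 2
  tr2 <- accel_trace(c_ * tr$ax, c_ * tr$ay, c_ * tr$az, fs = tr$fs)
  pre1 <- preprocess_trace(tr)
  pre2 <- preprocess_trace(tr2)
  n0 <- pre1$onset$n_start
  th1 <- calibrate_gait(pre1$jerk, n0)$thresholds
  th2 <- calibrate_gait(pre2$jerk, n0)$thresholds
  expect_equal(th2$TH2, c_ * th1$TH2, tolerance = 1e-8)
  expect_equal(th2$TH3, c_ * th1$TH3, tolerance = 1e-8)
  expect_equal(th2$TH4, c_ * th1$TH4, tolerance = 1e-8)
  expect_equal(th2$T_swin, th1$T_swin)
  expect_equal(th2$T_std, th1$T_std)
})

test_that("the calibration report serialises scales, events and thresholds", {
  trial <- cached_trial("level", seed = 21, noise = 0)
  pre <- preprocess_trace(trial$accel)
  cal <- calibrate_gait(pre$jerk, pre$onset$n_start)
  js <- jsonlite::fromJSON(calibration_report(cal))
  expect_equal(js$thresholds$TH2, cal$thresholds$TH2)
  expect_equal(nrow(js$events), nrow(cal$events))
  expect_equal(js$scales$mu_e_hat, cal$scales$mu_e_hat)
})
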