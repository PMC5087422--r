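# Streaming detector: peak confirmation and membership gating.

stream_events <- function(J, th, last_kind = "TO", last_t = -10,
                          wait_len = 15, start = 1) {
  run_stream(jerk_trace(J, FS, 1), th, start = start,
             last_event = last_event_at(last_kind, last_t),
             wait_len = wait_len, smooth_m = 1)
}

# J with peaks of given amplitudes at given indices (triangular bumps)
peaky <- function(n, at, amp, width = 3) {
  J <- rep(0.01, n)
  for (i in seq_along(at)) {
    k <- at[i]
    J[k] <- amp[i]
    for (w in 1:width) {
      up <- amp[i] * (1 - w / (width + 1))
      if (k - w >= 1) J[k - w] <- pmax(J[k - w], up)
      if (k + w <= n) J[k + w] <- pmax(J[k + w], up)
    }
  }
  J
}

test_that("a peak below the baseline membership never fires", {
  th <- make_thresholds(TH2 = 10, TH3 = 4, TH4 = 3)
  J <- peaky(200, at = 100, amp = 0.5 * th$r_b * th$TH2)
  expect_identical(nrow(stream_events(J, th)), 0L)
})

test_that("a larger peak inside the wait restarts the confirmation", {
  th <- make_thresholds(TH2 = 1, TH3 = 4, TH4 = 3, T_swin = 0.05)
  J <- peaky(200, at = c(100, 108), amp = c(3.0, 3.5))
  ev <- stream_events(J, th, last_kind = "TO", last_t = -10)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "HS")
  expect_identical(ev$n, 108L) # the second, larger peak wins
})

test_that("the duration membership gates a too-early candidate", {
  th <- make_thresholds(TH2 = 0.5, TH3 = 4, TH4 = 3, T_swin = 1.0)
  # candidate 0.4 * T_swin after the last TO: rejected
  at_early <- as.integer(round(0.4 * th$T_swin * FS)) + 1L
  J <- peaky(300, at = at_early, amp = 5)
  ev <- stream_events(J, th, last_kind = "TO", last_t = 0)
  expect_identical(nrow(ev), 0L)
  # same peak 0.6 * T_swin after: accepted
  at_late <- as.integer(round(0.6 * th$T_swin * FS)) + 1L
  J2 <- peaky(300, at = at_late, amp = 5)
  ev2 <- stream_events(J2, th, last_kind = "TO", last_t = 0)
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$n, at_late)
})

test_that("the amplitude membership uses the expected kind's threshold", {
  th <- make_thresholds(TH2 = 0.5, TH3 = 8, TH4 = 2, T_swin = 0.05,
                        T_std = 0.05)
  J <- peaky(200, at = 100, amp = 3) # 3 < r1*TH3 = 4, but > r1*TH4 = 1
  expect_identical(nrow(stream_events(J, th, last_kind = "TO")), 0L)
  ev <- stream_events(J, th, last_kind = "HS")
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "TO")
})

test_that("emitted kinds strictly alternate, starting opposite the last event", {
  trial <- cached_trial("level", seed = 31)
  fit <- gait_detect(trial)
  ev <- fit$events
  expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
  streamed <- ev[ev$source == "stream", ]
  last_cal <- fit$calibration$events$kind[nrow(fit$calibration$events)]
  expect_false(streamed$kind[1] == last_cal)
})

test_that("decisions are causal: truncating the stream preserves early emissions", {
  trial <- cached_trial("level", seed = 32)
  pre <- preprocess_trace(trial$accel)
  cal <- calibrate_gait(pre$jerk, pre$onset$n_start)
  start <- cal$window[2] + 1L
  full <- run_stream(pre$jerk, cal, start = start)
  n_cut <- start + 600L
  jerk_cut <- jerk_trace(pre$jerk$J[1:n_cut], FS, pre$jerk$m)
  part <- run_stream(jerk_cut, cal, start = start)
  wait <- 15L
  early <- full[full$n <= n_cut - wait, , drop = FALSE]
  expect_equal(part[seq_len(nrow(early)), c("kind", "n", "t")],
               early[, c("kind", "n", "t")])
})

test_that("raising r1 or r2 never increases the number of emitted events", {
  set.seed(33)
  for (rep in 1:5) {
    J <- pmax(0, cumsum(rnorm(800, sd = 0.3)) + 3 + 2 * sin((1:800) / 20))
    base <- make_thresholds(TH2 = mean(J), TH3 = max(J) * 0.8,
                            TH4 = max(J) * 0.6, T_swin = 0.3, T_std = 0.4)
    count <- function(r1, r2) {
      th <- base
      th$r1 <- r1
      th$r2 <- r2
      nrow(stream_events(J, th))
    }
    n_r1 <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), count, numeric(1), r2 = 0.5)
    n_r2 <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), count, numeric(1), r1 = 0.5)
    expect_true(all(diff(n_r1) <= 0))
    expect_true(all(diff(n_r2) <= 0))
  }
})

test_that("with no wait and open gates the detector emits every positive local maximum", {
  set.seed(34)
  J <- abs(rnorm(300))
  th <- make_thresholds(TH2 = 0, TH3 = 0, TH4 = 0, T_swin = 1e-9,
                        T_std = 1e-9)
  th$r_b <- 0; th$r1 <- 0; th$r2 <- 0
  ev <- stream_events(J, th, wait_len = 0)
  pk <- gaitwave:::local_extrema(J, "max")
  pk <- pk[J[pk] > 0]
  expect_identical(ev$n, pk[pk < 300]) # the final sample cannot confirm a peak
})

test_that("replaying the calibration window reproduces the window events", {
  trial <- cached_trial("level", seed = 21, noise = 0)
  pre <- preprocess_trace(trial$accel)
  cal <- calibrate_gait(pre$jerk, pre$onset$n_start)
  win_ev <- cal$events
  first <- win_ev[1, ]
  seed_ev <- data.frame(kind = setdiff(c("HS", "TO"), first$kind),
                        n = 1L, t = first$t - 0.45, amplitude = 1,
                        stringsAsFactors = FALSE)
  replay <- run_stream(pre$jerk, cal$thresholds, start = cal$window[1],
                       last_event = seed_ev, wait_len = 15, smooth_m = 30)
  replay <- replay[replay$n <= cal$window[2], , drop = FALSE]
  expect_gte(nrow(replay), nrow(win_ev) - 1)
  for (i in seq_len(nrow(replay))) {
    j <- which.min(abs(win_ev$n - replay$n[i]))
    expect_lte(abs(win_ev$n[j] - replay$n[i]), 2)
    expect_identical(win_ev$kind[j], replay$kind[i])
  }
})

test_that("stream over a noiseless walk matches ground truth with uniform latency", {
  trial <- cached_trial("level", seed = 35, noise = 0)
  fit <- gait_detect(trial)
  streamed <- fit$events[fit$events$source == "stream", ]
  truth_post <- trial$truth[trial$truth$t >
                              (fit$calibration$window[2] - 1) / FS, ]
  # every post-window truth event except possibly the final one is found
  m <- match_events(streamed, truth_post, tolerance = 0.4)
  expect_lte(m$counts$pooled[["FN"]], 1)
  expect_identical(m$counts$pooled[["FP"]],
                   nrow(streamed) - m$counts$pooled[["TP"]])
  # the detection lag is positive and consistent across events of a kind
  d <- m$pairs$diff_ms
  expect_true(all(d > 0 & d < 400))
  expect_lt(stats::sd(d), 50)
})

test_that("empty post-calibration stream and bad initialisation are errors or empty", {
  th <- make_thresholds()
  empty <- run_stream(jerk_trace(numeric(10), FS, 1), th, start = 11,
                      last_event = last_event_at())
  expect_identical(nrow(empty), 0L)
  expect_error(detector_init(th, NULL, FS), "last calibration event")
  st <- detector_init(th, last_event_at(), FS)
  r <- detector_step(st, 5L, 1)
  expect_error(detector_step(r$state, 5L, 1), "strictly increasing")
})
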