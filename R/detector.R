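# Streaming gait-event detector: candidate-peak tracking with a
# fixed-length confirmation wait and amplitude/duration membership gates.

#' Initialise the streaming detector
#'
#' The detector needs a calibrated [compute_thresholds()] result and the
#' last event found in the observation window (the next emitted event must
#' be of the opposite kind and far enough in time from it).
#'
#' @param thresholds a `threshold_set`.
#' @param last_event one-row gait-event data frame (fields `kind`, `t`).
#' @param fs sampling frequency (Hz).
#' @param wait_len confirmation wait in samples (default 15).
#' @param smooth_m smoothing window length used for the jerk trace; its
#'   group delay `(m-1)/2` samples is added to the reported latency.
#' @return A `detector_state` list.
#' @export
detector_init <- function(thresholds, last_event, fs, wait_len = 15,
                          smooth_m = 30) {
  stopifnot(inherits(thresholds, "threshold_set"))
  if (is.null(last_event) || !nrow(last_event)) {
    stop("detector needs the last calibration event (run calibrate_gait first)")
  }
  if (wait_len < 0) stop("`wait_len` must be >= 0")
  le <- last_event[nrow(last_event), ]
  structure(
    list(
      thresholds = thresholds, fs = fs,
      wait_len = as.integer(wait_len), smooth_m = as.integer(smooth_m),
      phase = "SEARCH",
      np_i = NA_integer_, np_amp = NA_real_, confirm_until = NA_integer_,
      last_kind = le$kind, last_t = le$t,
      # rising-edge tracker for causal peak detection
      prev = NA_real_, level_start = NA_integer_, ascending = FALSE,
      n_prev = NA_integer_
    ),
    class = "detector_state"
  )
}

#' Advance the detector by one sample
#'
#' Implements the streaming heuristic. In SEARCH, a local peak of the
#' smoothed jerk whose amplitude exceeds `r_b * TH2` becomes the starting
#' point and opens a confirmation wait of `wait_len` samples. During the
#' wait, any sample exceeding the starting point restarts the wait with the
#' larger value. When the wait expires unbeaten, the starting point becomes
#' the candidate peak and the membership gate applies: the expected kind is
#' the opposite of the last event; the candidate is accepted iff its
#' amplitude exceeds `r1 * TH3` (HS) or `r1 * TH4` (TO) *and* the elapsed
#' time since the last event exceeds `r2 * T_swin` (before HS) or
#' `r2 * T_std` (before TO). Accepted events are timestamped at the peak
#' index (the decision is `wait_len` samples later); rejected candidates are
#' discarded and the search restarts.
#'
#' @param state a `detector_state`.
#' @param n 1-based sample index; must increase by 1 per call.
#' @param J_n smoothed jerk value at `n` (g/s).
#' @return A list with `state` (updated) and `event` (one-row gait-event
#'   data frame with `latency_ms`, or `NULL`).
#' @export
detector_step <- function(state, n, J_n) {
  if (!is.na(state$n_prev) && n <= state$n_prev) {
    stop("sample index must be strictly increasing")
  }
  th <- state$thresholds
  event <- NULL

  # causal local-peak detection: a peak is known one sample after its apex;
  # a plateau resolves to its first sample once the signal drops.
  # `level_start` tracks the first sample of the current level run (set on a
  # strict rise, kept on equality).
  peak_i <- NA_integer_
  peak_amp <- NA_real_
  if (is.na(state$prev)) {
    state$ascending <- FALSE
    state$level_start <- n
  } else if (J_n > state$prev) {
    state$ascending <- TRUE
    state$level_start <- n
  } else if (J_n < state$prev) {
    if (state$ascending) {
      peak_i <- state$level_start
      peak_amp <- state$prev
    }
    state$ascending <- FALSE
    state$level_start <- n
  }

  if (state$phase == "SEARCH") {
    if (!is.na(peak_i) && peak_amp > th$r_b * th$TH2) {
      state$phase <- "CONFIRM"
      state$np_i <- peak_i
      state$np_amp <- peak_amp
      state$confirm_until <- peak_i + state$wait_len
    }
  } else if (state$phase == "CONFIRM") {
    if (J_n > state$np_amp) {
      state$np_i <- n
      state$np_amp <- J_n
      state$confirm_until <- n + state$wait_len
    }
  }

  if (state$phase == "CONFIRM" && n >= state$confirm_until) {
    expected <- if (state$last_kind == "TO") "HS" else "TO"
    amp_th <- th$r1 * if (expected == "HS") th$TH3 else th$TH4
    dur_th <- th$r2 * if (expected == "HS") th$T_swin else th$T_std
    t_peak <- (state$np_i - 1) / state$fs
    if (state$np_amp > amp_th && (t_peak - state$last_t) > dur_th) {
      latency_ms <- (n - state$np_i + (state$smooth_m - 1) / 2) /
        state$fs * 1000
      event <- data.frame(kind = expected, n = state$np_i, t = t_peak,
                          amplitude = state$np_amp,
                          latency_ms = latency_ms,
                          stringsAsFactors = FALSE)
      state$last_kind <- expected
      state$last_t <- t_peak
    }
    state$phase <- "SEARCH"
    state$np_i <- NA_integer_
    state$np_amp <- NA_real_
    state$confirm_until <- NA_integer_
  }

  state$prev <- J_n
  state$n_prev <- n
  list(state = state, event = event)
}

#' Run the streaming detector over a jerk trace
#'
#' Folds [detector_step()] over the samples from `start` onward and collects
#' the emitted events. The reported per-event latency is the confirmation
#' wait plus the group delay of the jerk smoothing window.
#'
#' @param jerk a [jerk_trace()].
#' @param thresholds a `threshold_set`.
#' @param start first sample to stream (typically one past the observation
#'   window).
#' @param last_event last calibration event (one-row gait-event data frame);
#'   defaults to the last row of `calibration$events` when a
#'   `gait_calibration` is given as `thresholds`.
#' @param wait_len confirmation wait in samples (default 15).
#' @param smooth_m smoothing window length (defaults to the trace's `m`).
#' @return A gait-event data frame (`kind`, `n`, `t`, `amplitude`,
#'   `latency_ms`), possibly empty.
#' @export
run_stream <- function(jerk, thresholds, start, last_event = NULL,
                       wait_len = 15, smooth_m = jerk$m) {
  stopifnot(inherits(jerk, "jerk_trace"))
  if (inherits(thresholds, "gait_calibration")) {
    cal <- thresholds
    thresholds <- cal$thresholds
    if (is.null(last_event)) last_event <- cal$events[nrow(cal$events), ]
  }
  state <- detector_init(thresholds, last_event, fs = jerk$fs,
                         wait_len = wait_len, smooth_m = smooth_m)
  n_total <- length(jerk$J)
  out <- vector("list", 64L)
  k <- 0L
  if (start <= n_total) {
    # seed the edge tracker with the sample before `start` so a peak at
    # `start` itself is not missed (value is still causal)
    if (start > 1L) {
      state$prev <- jerk$J[start - 1L]
      state$n_prev <- start - 1L
      state$level_start <- start - 1L
    }
    for (n in start:n_total) {
      res <- detector_step(state, n, jerk$J[n])
      state <- res$state
      if (!is.null(res$event)) {
        k <- k + 1L
        if (k > length(out)) out <- c(out, vector("list", length(out)))
        out[[k]] <- res$event
      }
    }
  }
  if (k == 0L) {
    return(data.frame(kind = character(0), n = integer(0), t = numeric(0),
                      amplitude = numeric(0), latency_ms = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, out[seq_len(k)])
  rownames(ev) <- NULL
  ev
}
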