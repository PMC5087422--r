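# From raw acceleration to the smoothed jerk signal and the walking onset.

#' Zero-phase high-pass filter of an accelerometer trace
#'
#' Removes the gravity component and slow drift from each axis with a
#' Butterworth high-pass applied forward and backward (zero phase). The
#' effective magnitude response is the square of the single-pass response, so
#' the cutoff frequency is attenuated to 0.5 in amplitude rather than
#' 1/sqrt(2).
#'
#' @param trace an [accel_trace()].
#' @param cutoff cutoff frequency in Hz (default 0.5).
#' @param order filter order (default 2).
#' @return A filtered [accel_trace()] of the same length.
#' @export
highpass_accel <- function(trace, cutoff = 0.5, order = 2) {
  stopifnot(inherits(trace, "accel_trace"))
  n <- length(trace$ax)
  if (n <= 3L * order + 1L) {
    stop(sprintf("trace too short for order-%d filtering: need more than %d samples, got %d",
                 order, 3L * order + 1L, n))
  }
  if (cutoff <= 0 || cutoff >= trace$fs / 2) {
    stop("`cutoff` must lie in (0, fs/2)")
  }
  bf <- signal::butter(order, cutoff / (trace$fs / 2), type = "high")
  accel_trace(
    ax = filtfilt_ss(bf, trace$ax),
    ay = filtfilt_ss(bf, trace$ay),
    az = filtfilt_ss(bf, trace$az),
    fs = trace$fs, t = trace$t
  )
}

#' Composite (vector-magnitude) acceleration
#'
#' `sqrt(ax^2 + ay^2 + az^2)` per sample, in g.
#'
#' @param trace an [accel_trace()].
#' @return Non-negative numeric vector, same length as the trace.
#' @export
composite_acceleration <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
}

#' Detect the rest-to-walking transition
#'
#' The walking onset is the first sample at which the composite acceleration
#' of the (high-pass filtered) trace exceeds the threshold `th1`. During
#' quiet standing the filtered composite magnitude stays near zero, so a
#' threshold of 1 g is only crossed by an actual movement burst.
#'
#' @param cacc composite acceleration vector (g), from
#'   [composite_acceleration()] on the filtered trace.
#' @param th1 onset threshold in g (default 1).
#' @return A list with `n_start` (1-based sample index, or `NA_integer_` if
#'   the threshold is never exceeded) and `threshold_used`.
#' @export
detect_onset <- function(cacc, th1 = 1.0) {
  idx <- which(cacc > th1)
  n_start <- if (length(idx)) idx[1L] else NA_integer_
  list(n_start = n_start, threshold_used = th1)
}

#' Jerk magnitude of a trace
#'
#' Per-axis backward first difference scaled by the sampling rate
#' (`(a[n] - a[n-1]) * fs`), combined as a Euclidean magnitude across the
#' three axes. The first output sample is defined as 0 so the length is
#' preserved; the estimator is causal.
#'
#' @param trace an [accel_trace()] with at least 2 samples.
#' @return Non-negative numeric vector (g/s), same length as the trace.
#' @export
jerk_magnitude <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  n <- length(trace$ax)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  dx <- c(0, diff(trace$ax)) * trace$fs
  dy <- c(0, diff(trace$ay)) * trace$fs
  dz <- c(0, diff(trace$az)) * trace$fs
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Trailing moving average
#'
#' Causal mean over the last `m` samples (window `[n-m+1, n]`). During
#' warm-up (`n < m`) the mean is taken over the samples seen so far rather
#' than divided by `m`, which avoids a spurious startup ramp.
#'
#' @param x numeric vector.
#' @param m window length in samples (default 30).
#' @return Numeric vector of the same length.
#' @export
moving_average <- function(x, m = 30) {
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1")
  n <- length(x)
  if (m == 1L || n == 0L) return(as.numeric(x))
  cs <- cumsum(x)
  out <- numeric(n)
  head_n <- seq_len(min(m - 1L, n))
  out[head_n] <- cs[head_n] / head_n
  if (n >= m) {
    idx <- m:n
    out[idx] <- (cs[idx] - c(0, cs)[idx - m + 1L]) / m
  }
  out
}

#' Preprocess a trace for gait-event detection
#'
#' Convenience wrapper running the full front end: zero-phase high-pass
#' filtering, composite acceleration, walking-onset detection, jerk
#' magnitude, and moving-average smoothing.
#'
#' @param trace an [accel_trace()].
#' @param config a [gait_config()] list.
#' @return A list with `trace_f` (filtered trace), `cacc`, `onset` (from
#'   [detect_onset()]) and `jerk` (a [jerk_trace()]).
#' @export
preprocess_trace <- function(trace, config = gait_config()) {
  trace_f <- highpass_accel(trace, cutoff = config$hp_cutoff,
                            order = config$hp_order)
  cacc <- composite_acceleration(trace_f)
  onset <- detect_onset(cacc, th1 = config$th1)
  raw_jerk <- jerk_magnitude(trace_f)
  J <- moving_average(raw_jerk, m = config$smooth_m)
  list(trace_f = trace_f, cacc = cacc, onset = onset,
       jerk = jerk_trace(J, fs = trace$fs, m = config$smooth_m))
}
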