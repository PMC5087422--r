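# Containers for raw sensor recordings.

#' Tri-axial accelerometer trace
#'
#' Bundles the three acceleration axes (in units of g) with the sampling
#' frequency and sample times. All downstream processing starts from this
#' container.
#'
#' @param ax,ay,az numeric vectors of per-axis acceleration (g), equal length
#'   of at least 2.
#' @param fs sampling frequency in Hz (> 0).
#' @param t optional sample times in seconds; defaults to `(0:(n-1))/fs`.
#'   Must be strictly increasing with spacing `1/fs` (tolerance 1e-6 s).
#' @return An object of class `accel_trace` with fields `fs`, `t`, `ax`,
#'   `ay`, `az`.
#' @examples
#' tr <- accel_trace(ax = rnorm(100, sd = 0.01), ay = rnorm(100, sd = 0.01),
#'                   az = 1 + rnorm(100, sd = 0.01), fs = 148.15)
#' tr
#' @export
accel_trace <- function(ax, ay, az, fs, t = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  n <- length(ax)
  if (n < 2L) stop("trace must contain at least 2 samples")
  if (length(ay) != n || length(az) != n) {
    stop("`ax`, `ay`, `az` must have equal length")
  }
  if (is.null(t)) {
    t <- (seq_len(n) - 1) / fs
  } else {
    if (length(t) != n) stop("`t` must match the axis length")
    dt <- diff(t)
    if (any(dt <= 0)) stop("`t` must be strictly increasing")
    if (any(abs(dt - 1 / fs) > 1e-6)) {
      stop("sample spacing of `t` inconsistent with `fs` (tolerance 1e-6 s)")
    }
  }
  structure(
    list(fs = fs, t = as.numeric(t),
         ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az)),
    class = "accel_trace"
  )
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace: %d samples @ %.2f Hz (%.2f s)>\n",
              length(x$ax), x$fs, length(x$ax) / x$fs))
  invisible(x)
}

#' @export
length.accel_trace <- function(x) length(x$ax)

#' Smoothed jerk-magnitude trace
#'
#' Holds the moving-average-smoothed jerk magnitude `J(n)` (g/s), the signal
#' all event detection operates on.
#'
#' @param J non-negative numeric vector (g/s).
#' @param fs sampling frequency (Hz).
#' @param m smoothing window length in samples.
#' @return An object of class `jerk_trace`.
#' @export
jerk_trace <- function(J, fs, m) {
  if (any(J < 0)) stop("jerk magnitude must be non-negative")
  if (fs <= 0) stop("`fs` must be positive")
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1")
  structure(list(fs = fs, J = as.numeric(J), m = m), class = "jerk_trace")
}

#' @export
print.jerk_trace <- function(x, ...) {
  cat(sprintf("<jerk_trace: %d samples @ %.2f Hz, smoothing m = %d>\n",
              length(x$J), x$fs, x$m))
  invisible(x)
}

#' Read an accelerometer (and optional FSR) trace from CSV
#'
#' Expects a comma-delimited file with a header containing at least
#' `time_s, ax_g, ay_g, az_g`; optional columns `fsr_heel`, `fsr_toe` are
#' returned as an [fsr_trace()]. The sampling rate is inferred from the time
#' column and, when `fs` is supplied, validated against it.
#'
#' @param path file path.
#' @param fs optional expected sampling frequency (Hz); a mismatch beyond
#'   0.5\% is an error.
#' @return A list with elements `trace` ([accel_trace()]) and `fsr`
#'   ([fsr_trace()] or `NULL`).
#' @export
read_trace_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  counts <- utils::count.fields(path, sep = ",")
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1L])[1L]
    stop(sprintf("malformed CSV row at line %d of %s", bad, path))
  }
  df <- utils::read.csv(path)
  need <- c("time_s", "ax_g", "ay_g", "az_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  fs_hat <- 1 / stats::median(diff(df$time_s))
  if (!is.null(fs) && abs(fs_hat - fs) / fs > 0.005) {
    stop(sprintf("sampling rate in file (%.3f Hz) disagrees with expected %.3f Hz",
                 fs_hat, fs))
  }
  fs_use <- fs %||% fs_hat
  trace <- accel_trace(df$ax_g, df$ay_g, df$az_g, fs = fs_use, t = df$time_s)
  fsr <- NULL
  if (all(c("fsr_heel", "fsr_toe") %in% names(df))) {
    fsr <- fsr_trace(df$fsr_heel, df$fsr_toe, fs = fs_use)
  }
  list(trace = trace, fsr = fsr)
}

#' Write a trace (and optional FSR channels) to CSV
#'
#' Inverse of [read_trace_csv()]; fixed dialect (comma, header, `.` decimal).
#'
#' @param trace an [accel_trace()].
#' @param path output file path.
#' @param fsr optional [fsr_trace()] of the same length.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, fsr = NULL) {
  df <- data.frame(time_s = trace$t, ax_g = trace$ax, ay_g = trace$ay,
                   az_g = trace$az)
  if (!is.null(fsr)) {
    stopifnot(length(fsr$heel) == length(trace$ax))
    df$fsr_heel <- fsr$heel
    df$fsr_toe <- fsr$toe
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write detected gait events to CSV
#'
#' Columns: `kind, n, t_s, amplitude` and, when present, `latency_ms`.
#'
#' @param events a gait-event data frame (`kind`, `n`, `t`, `amplitude`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  out <- data.frame(kind = events$kind, n = events$n, t_s = events$t,
                    amplitude = events$amplitude)
  if (!is.null(events$latency_ms)) out$latency_ms <- events$latency_ms
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read gait events written by [write_events_csv()]
#'
#' @param path file path.
#' @return A gait-event data frame with columns `kind`, `n`, `t`,
#'   `amplitude` (and `latency_ms` when present).
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(kind = df$kind, n = df$n, t = df$t_s,
                    amplitude = df$amplitude, stringsAsFactors = FALSE)
  if (!is.null(df$latency_ms)) out$latency_ms <- df$latency_ms
  out
}
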