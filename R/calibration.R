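# Observation-window calibration: band extraction, in-window event
# detection, and threshold estimation for the streaming detector.

#' Extract event- and cycle-band signals from a scalogram
#'
#' Takes the real part of the wavelet coefficients at the posterior event
#' and cycle scales and smooths each with a zero-phase 2nd-order Butterworth
#' filter at `cutoff` Hz. The purpose of the filter is to remove
#' high-frequency noise, so the default is a low-pass; `type = "highpass"`
#' selects the literal alternative reading.
#'
#' @param scal a `scalogram` whose grid contains both scales.
#' @param est a `scale_estimate` from [split_and_refine()].
#' @param fs sampling frequency (Hz); defaults to the scalogram's.
#' @param cutoff filter cutoff in Hz (default 10).
#' @param type `"lowpass"` (default) or `"highpass"`.
#' @return A list with numeric vectors `x_e` and `x_c` (window length).
#' @export
extract_bands <- function(scal, est, fs = scal$fs, cutoff = 10,
                          type = c("lowpass", "highpass")) {
  type <- match.arg(type)
  stopifnot(inherits(scal, "scalogram"), inherits(est, "scale_estimate"))
  ie <- match(est$mu_e_hat, scal$scales)
  ic <- match(est$mu_c_hat, scal$scales)
  if (is.na(ie) || is.na(ic)) {
    stop("requested scale not on the scalogram grid")
  }
  x_e <- Re(scal$W[ie, ])
  x_c <- Re(scal$W[ic, ])
  if (!is.na(fs) && cutoff < fs / 2) {
    bf <- signal::butter(2, cutoff / (fs / 2),
                         type = if (type == "lowpass") "low" else "high")
    x_e <- filtfilt_ss(bf, x_e)
    x_c <- filtfilt_ss(bf, x_c)
  }
  list(x_e = x_e, x_c = x_c)
}

#' Segment an observation window into event regions
#'
#' Negative peaks of the event-band signal (local minima with value < 0)
#' divide the window into regions each expected to contain one gait event.
#' The first region runs from the window start to the first negative peak
#' and the last from the final negative peak to the window end; neighbouring
#' regions share their boundary sample.
#'
#' @param x_e event-band signal.
#' @return A list of integer pairs `c(start, end)` (1-based, inclusive).
#' @export
segment_regions <- function(x_e) {
  np <- local_extrema(x_e, "min")
  np <- np[x_e[np] < 0]
  if (!length(np)) {
    stop("no negative peak in the event band: window not calibratable")
  }
  n <- length(x_e)
  b <- unique(c(1L, np, n))
  if (length(b) < 2L) stop("window too short to segment")
  Map(function(a, z) c(a, z), b[-length(b)], b[-1L])
}

#' Detect gait events inside the observation window
#'
#' Each region's event time is the argmax of the smoothed jerk `J` within
#' the region (ties to the smallest index). The event kind comes from the
#' cycle band: HS when the largest-magnitude local extremum of `x_c` in the
#' region is a positive peak, TO when it is a negative peak. Regions with no
#' `x_c` extremum are excluded. Because a valid event sequence alternates,
#' consecutive same-kind events are repaired by dropping the lower-amplitude
#' one.
#'
#' @param J_win smoothed jerk over the window (g/s).
#' @param bands list with `x_e`, `x_c` from [extract_bands()].
#' @param fs sampling frequency (Hz).
#' @param n_offset global index of the sample before the window start
#'   (so global `n = n_offset + local index`); default 0.
#' @param min_amp baseline amplitude gate (g/s): regions whose jerk peak
#'   does not exceed it are excluded, mirroring the streaming detector's
#'   baseline membership. Default 0 (no gate).
#' @return A gait-event data frame: columns `kind` ("HS"/"TO"), `n` (global
#'   sample index), `t` (s), `amplitude` (g/s), sorted by time.
#' @export
detect_window_events <- function(J_win, bands, fs, n_offset = 0L,
                                 min_amp = 0) {
  regions <- segment_regions(bands$x_e)
  x_c <- bands$x_c
  rows <- lapply(regions, function(r) {
    seg <- r[1L]:r[2L]
    peak_local <- seg[which.max(J_win[seg])]
    if (J_win[peak_local] <= min_amp) return(NULL)
    # kind from the dominant local extremum of the cycle band in the region
    ext <- c(local_extrema(x_c[seg], "max"), local_extrema(x_c[seg], "min"))
    if (!length(ext)) return(NULL)
    ext_global <- seg[ext]
    dom <- ext_global[which.max(abs(x_c[ext_global]))]
    kind <- if (x_c[dom] > 0) "HS" else "TO"
    data.frame(kind = kind, n = n_offset + peak_local,
               t = (n_offset + peak_local - 1) / fs,
               amplitude = J_win[peak_local], stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  if (is.null(ev) || !nrow(ev)) stop("no classifiable event region in window")
  ev <- ev[order(ev$t), , drop = FALSE]
  ev <- ev[!duplicated(ev$n), , drop = FALSE]
  repair_alternation(ev)
}

# Leave-one-out amplitude-consistency filter: a window event whose peak
# falls at or below r1 x the mean amplitude of the *other* events of its
# kind would never pass the streaming amplitude membership, so it is
# treated as a segmentation artefact (typically a partial edge region) and
# dropped. Falls back to the unfiltered set if filtering would leave the
# window uncalibratable (missing a kind or an adjacent pair type).
filter_window_events <- function(ev, r1) {
  out <- ev
  repeat {
    dropped <- FALSE
    for (k in c("HS", "TO")) {
      idx <- which(out$kind == k)
      if (length(idx) < 2L) next
      for (i in idx) {
        others <- setdiff(idx, i)
        if (out$amplitude[i] <= r1 * mean(out$amplitude[others])) {
          out <- out[-i, , drop = FALSE]
          dropped <- TRUE
          break
        }
      }
      if (dropped) break
    }
    if (!dropped) break
  }
  out <- repair_alternation(out)
  k <- out$kind
  ok <- any(k == "HS") && any(k == "TO") &&
    any(k[-length(k)] == "TO" & k[-1L] == "HS") &&
    any(k[-length(k)] == "HS" & k[-1L] == "TO")
  if (ok) out else ev
}

# Drop the lower-amplitude offender of each consecutive same-kind run.
repair_alternation <- function(ev) {
  repeat {
    if (nrow(ev) < 2L) break
    same <- which(ev$kind[-1L] == ev$kind[-nrow(ev)])
    if (!length(same)) break
    i <- same[1L]
    drop <- if (ev$amplitude[i] <= ev$amplitude[i + 1L]) i else i + 1L
    ev <- ev[-drop, , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

#' Compute detector thresholds from window events
#'
#' * `TH2` - median of the smoothed jerk over the window (baseline),
#' * `TH3` / `TH4` - mean peak amplitude of the HS / TO events,
#' * `T_swin` - mean TO-to-HS (swing) interval,
#' * `T_std` - mean HS-to-TO (stance) interval,
#'
#' plus the membership fractions `r_b`, `r1`, `r2` taken from the
#' configuration.
#'
#' @param events gait-event data frame from [detect_window_events()].
#' @param J_win smoothed jerk over the window.
#' @param r_b baseline membership (default 0.8).
#' @param r1 stride amplitude membership (default 0.5).
#' @param r2 stride duration membership (default 0.5).
#' @return An object of class `threshold_set`.
#' @export
compute_thresholds <- function(events, J_win, r_b = 0.8, r1 = 0.5, r2 = 0.5) {
  if (any(c(r_b, r1, r2) <= 0) || any(c(r_b, r1, r2) > 1)) {
    stop("memberships r_b, r1, r2 must lie in (0, 1]")
  }
  hs <- events[events$kind == "HS", , drop = FALSE]
  to <- events[events$kind == "TO", , drop = FALSE]
  if (!nrow(hs)) stop("calibration failed: no HS event in observation window")
  if (!nrow(to)) stop("calibration failed: no TO event in observation window")
  k <- events$kind
  swing <- which(k[-length(k)] == "TO" & k[-1L] == "HS")
  stance <- which(k[-length(k)] == "HS" & k[-1L] == "TO")
  if (!length(swing)) stop("calibration failed: no TO->HS (swing) pair in window")
  if (!length(stance)) stop("calibration failed: no HS->TO (stance) pair in window")
  t_swin <- mean(events$t[swing + 1L] - events$t[swing])
  t_std <- mean(events$t[stance + 1L] - events$t[stance])
  structure(
    list(TH2 = stats::median(J_win), TH3 = mean(hs$amplitude),
         TH4 = mean(to$amplitude), T_swin = t_swin, T_std = t_std,
         r_b = r_b, r1 = r1, r2 = r2),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>\n")
  cat(sprintf("  TH2 (baseline)   : %.3f g/s\n", x$TH2))
  cat(sprintf("  TH3 (HS peaks)   : %.3f g/s\n", x$TH3))
  cat(sprintf("  TH4 (TO peaks)   : %.3f g/s\n", x$TH4))
  cat(sprintf("  T_swin / T_std   : %.3f / %.3f s\n", x$T_swin, x$T_std))
  cat(sprintf("  r_b / r1 / r2    : %.2f / %.2f / %.2f\n", x$r_b, x$r1, x$r2))
  invisible(x)
}

#' Calibrate the detector from one observation window
#'
#' Runs the full time-frequency calibration on the smoothed jerk: Morlet
#' scalogram of the window, observed scale-energy spectrum, cross-correlation
#' against the two-Gaussian prior to get the scale delay, valley split and
#' posterior event/cycle scales, band extraction, in-window event detection,
#' and threshold computation.
#'
#' @param jerk a [jerk_trace()] for the whole recording.
#' @param n_start walking-onset index (1-based), e.g. from [detect_onset()].
#' @param config a [gait_config()] list.
#' @return An object of class `gait_calibration` with fields `window`
#'   (`c(start, end)` indices), `scales` (a `scale_estimate`), `energy`
#'   (observed spectrum), `bands`, `events` (in-window gait events, global
#'   indices) and `thresholds` (a `threshold_set`).
#' @export
calibrate_gait <- function(jerk, n_start, config = gait_config()) {
  stopifnot(inherits(jerk, "jerk_trace"))
  wl <- config$window_len
  if (is.na(n_start)) stop("no walking onset: cannot place observation window")
  if (n_start + wl - 1L > length(jerk$J)) {
    stop(sprintf("trace ends before the observation window: need %d samples after onset %d",
                 wl, n_start))
  }
  win <- c(n_start, n_start + wl - 1L)
  J_win <- jerk$J[win[1L]:win[2L]]
  # centre the window before the transform: with zero-padded boundaries the
  # large positive offset of J would otherwise look like a boxcar and flood
  # the large scales with edge energy
  scal <- cwt_morlet(J_win - mean(J_win),
                     scales = seq_len(config$s_max),
                     params = morlet_params(config$fc))
  e_obs <- energy_spectrum(scal)
  e_prior <- prior_energy_spectrum(config$s_max, config$prior_mu_e,
                                   config$prior_mu_c, config$prior_sigma1,
                                   config$prior_sigma2)
  tau <- scale_delay(e_prior, e_obs)
  est <- split_and_refine(e_obs, tau, config$prior_mu_e, config$prior_mu_c)
  bands <- extract_bands(scal, est, fs = jerk$fs,
                         cutoff = config$band_cutoff,
                         type = config$band_filter)
  events <- detect_window_events(J_win, bands, fs = jerk$fs,
                                 n_offset = win[1L] - 1L,
                                 min_amp = config$r_b * stats::median(J_win))
  events <- filter_window_events(events, r1 = config$r1)
  thresholds <- compute_thresholds(events, J_win, r_b = config$r_b,
                                   r1 = config$r1, r2 = config$r2)
  structure(
    list(window = win, scales = est, energy = e_obs, bands = bands,
         events = events, thresholds = thresholds, fs = jerk$fs),
    class = "gait_calibration"
  )
}

#' @export
print.gait_calibration <- function(x, ...) {
  cat(sprintf("<gait_calibration: window [%d, %d] @ %.2f Hz>\n",
              x$window[1L], x$window[2L], x$fs))
  print(x$scales)
  cat(sprintf("  %d window events (%s)\n", nrow(x$events),
              paste(x$events$kind, collapse = " ")))
  print(x$thresholds)
  invisible(x)
}

#' @export
coef.gait_calibration <- function(object, ...) {
  th <- object$thresholds
  c(TH2 = th$TH2, TH3 = th$TH3, TH4 = th$TH4,
    T_swin = th$T_swin, T_std = th$T_std,
    r_b = th$r_b, r1 = th$r1, r2 = th$r2)
}

#' Serialise a calibration to JSON-structured text
#'
#' @param cal a `gait_calibration`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to file).
#' @export
calibration_report <- function(cal, path = NULL) {
  stopifnot(inherits(cal, "gait_calibration"))
  obj <- list(
    window = cal$window,
    scales = unclass(cal$scales),
    events = cal$events,
    thresholds = unclass(cal$thresholds)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
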