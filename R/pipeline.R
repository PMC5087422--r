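# Configuration and the end-to-end pipeline.

config_ranges <- list(
  fs = c(1, 10000), hp_cutoff = c(1e-3, 50), hp_order = c(1, 8),
  smooth_m = c(1, 1000), th1 = c(1e-6, 100), window_len = c(10, 1e5),
  fc = c(1e-3, 100), s_max = c(2, 5000),
  prior_mu_e = c(1, 5000), prior_mu_c = c(1, 5000),
  prior_sigma1 = c(1e-6, 1000), prior_sigma2 = c(1e-6, 1000),
  band_cutoff = c(1e-3, 1000), wait_len = c(0, 1000),
  r_b = c(1e-9, 1), r1 = c(1e-9, 1), r2 = c(1e-9, 1),
  match_tolerance = c(1e-3, 10)
)

#' Pipeline configuration
#'
#' Returns the default parameter set of the detector, with any overrides
#' applied and range-checked. Defaults: 148.15 Hz sampling, 0.5 Hz
#' 2nd-order high-pass, 30-sample jerk smoothing, 1 g onset threshold,
#' 300-sample observation window, Morlet centre frequency 0.8125 Hz on
#' scales 1..241, scale prior (75, 150) with spreads (15, 25), 10 Hz band
#' filter, 15-sample confirmation wait, memberships `r_b = 0.8`,
#' `r1 = r2 = 0.5`, and 400 ms event-matching tolerance.
#'
#' @param ... named overrides of the defaults; unknown names are rejected.
#' @return A named list of class `gait_config`.
#' @examples
#' gait_config(smooth_m = 10)$smooth_m
#' @export
gait_config <- function(...) {
  cfg <- list(
    fs = 148.15, hp_cutoff = 0.5, hp_order = 2L, smooth_m = 30L,
    th1 = 1.0, window_len = 300L, fc = 0.8125, s_max = 241L,
    prior_mu_e = 75L, prior_mu_c = 150L, prior_sigma1 = 15,
    prior_sigma2 = 25, band_cutoff = 10, band_filter = "lowpass",
    wait_len = 15L, r_b = 0.8, r1 = 0.5, r2 = 0.5, match_tolerance = 0.4
  )
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]])) {
    over <- over[[1L]]
  }
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  structure(cfg, class = "gait_config")
}

validate_config <- function(cfg) {
  for (key in names(config_ranges)) {
    rng <- config_ranges[[key]]
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v < rng[1L] || v > rng[2L]) {
      stop(sprintf("config key `%s` = %s out of range [%g, %g]",
                   key, format(cfg[[key]]), rng[1L], rng[2L]))
    }
  }
  if (!cfg$band_filter %in% c("lowpass", "highpass")) {
    stop("config key `band_filter` must be \"lowpass\" or \"highpass\"")
  }
  if (cfg$prior_mu_e >= cfg$prior_mu_c) stop("need prior_mu_e < prior_mu_c")
  if (cfg$prior_mu_c > cfg$s_max) stop("need prior_mu_c <= s_max")
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a YAML key-value file, merges it over the defaults, rejects
#' unknown keys and range-checks every value. An empty file yields the
#' default configuration.
#'
#' @param path file path.
#' @return A `gait_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  over <- yaml::read_yaml(path)
  if (is.null(over)) return(gait_config())
  if (!is.list(over)) stop("config file must contain key: value pairs")
  gait_config(over)
}

#' Detect gait events in a trace (full pipeline)
#'
#' Runs the three stages end to end: preprocessing (high-pass filter,
#' composite acceleration, walking onset, smoothed jerk), time-frequency
#' self-calibration on the observation window, and the streaming detector
#' over the remainder of the trace. When an FSR trace is supplied, reference
#' events are extracted and the detected stream is scored against them.
#'
#' @param x an [accel_trace()], a `synthetic_trial`, or a CSV path readable
#'   by [read_trace_csv()].
#' @param config a [gait_config()] list.
#' @param fsr optional [fsr_trace()] (taken from the trial or CSV when
#'   present).
#' @return An object of class `gait_fit`: list with `config`, `pre`
#'   (preprocessing output), `calibration` (a `gait_calibration`), `events`
#'   (all detected events, window + streamed, with a `source` column),
#'   `fsr_events` and `evaluation` (when FSR data were available), and
#'   `truth`/`truth_evaluation` for synthetic trials.
#' @examples
#' trial <- generate_trial(terrain_presets()$level, duration = 12, seed = 1)
#' fit <- gait_detect(trial)
#' fit
#' @export
gait_detect <- function(x, config = gait_config(), fsr = NULL) {
  truth <- NULL
  if (is.character(x)) {
    got <- read_trace_csv(x, fs = config$fs)
    trace <- got$trace
    if (is.null(fsr)) fsr <- got$fsr
  } else if (inherits(x, "synthetic_trial")) {
    trace <- x$accel
    if (is.null(fsr)) fsr <- x$fsr
    truth <- x$truth
  } else if (inherits(x, "accel_trace")) {
    trace <- x
  } else {
    stop("`x` must be an accel_trace, a synthetic_trial, or a CSV path")
  }
  if (abs(trace$fs - config$fs) / config$fs > 0.005) {
    stop(sprintf("trace sampling rate %.3f Hz disagrees with config fs %.3f Hz",
                 trace$fs, config$fs))
  }

  pre <- preprocess_trace(trace, config)
  cal <- calibrate_gait(pre$jerk, pre$onset$n_start, config)
  streamed <- run_stream(pre$jerk, cal$thresholds,
                         start = cal$window[2L] + 1L,
                         last_event = cal$events[nrow(cal$events), ],
                         wait_len = config$wait_len,
                         smooth_m = config$smooth_m)
  win_ev <- cal$events
  win_ev$latency_ms <- NA_real_
  win_ev$source <- "window"
  if (nrow(streamed)) streamed$source <- "stream"
  events <- rbind(win_ev, streamed)
  rownames(events) <- NULL

  fsr_events <- NULL
  evaluation <- NULL
  if (!is.null(fsr)) {
    fsr_events <- detect_fsr_events(fsr, window = cal$window)
    evaluation <- evaluate_events(events, fsr_events,
                                  tolerance = config$match_tolerance)
  }
  truth_evaluation <- NULL
  if (!is.null(truth)) {
    truth_evaluation <- evaluate_events(events, truth,
                                        tolerance = config$match_tolerance)
  }
  structure(
    list(config = config, pre = pre, calibration = cal, events = events,
         fsr_events = fsr_events, evaluation = evaluation,
         truth = truth, truth_evaluation = truth_evaluation),
    class = "gait_fit"
  )
}

#' @export
print.gait_fit <- function(x, ...) {
  cat(sprintf("<gait_fit: %d events (%d HS, %d TO), onset at sample %d>\n",
              nrow(x$events), sum(x$events$kind == "HS"),
              sum(x$events$kind == "TO"), x$pre$onset$n_start))
  print(x$calibration$thresholds)
  invisible(x)
}

#' @export
summary.gait_fit <- function(object, ...) {
  cat(sprintf("Gait-event detection fit (%d samples @ %.2f Hz)\n",
              length(object$pre$jerk$J), object$pre$jerk$fs))
  cat(sprintf("Walking onset: sample %d (%.2f s)\n", object$pre$onset$n_start,
              (object$pre$onset$n_start - 1) / object$pre$jerk$fs))
  print(object$calibration)
  lat <- object$events$latency_ms
  if (any(!is.na(lat))) {
    cat(sprintf("Streaming latency: %.0f ms (median)\n",
                stats::median(lat, na.rm = TRUE)))
  }
  if (!is.null(object$evaluation)) {
    cat("\nAgainst FSR reference:\n")
    print(object$evaluation)
  }
  if (!is.null(object$truth_evaluation)) {
    cat("\nAgainst simulator ground truth:\n")
    print(object$truth_evaluation)
  }
  invisible(object)
}

#' Plot a gait fit
#'
#' Smoothed jerk with the observation window shaded and detected events
#' marked (HS solid, TO dashed).
#'
#' @param x a `gait_fit`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.gait_fit <- function(x, ...) {
  J <- x$pre$jerk$J
  tt <- (seq_along(J) - 1) / x$pre$jerk$fs
  graphics::plot(tt, J, type = "l", xlab = "time (s)",
                 ylab = "smoothed jerk (g/s)", ...)
  win <- (x$calibration$window - 1) / x$pre$jerk$fs
  graphics::rect(win[1L], 0, win[2L], max(J), col = grDevices::adjustcolor("grey", 0.3),
                 border = NA)
  hs <- x$events[x$events$kind == "HS", ]
  to <- x$events[x$events$kind == "TO", ]
  graphics::abline(v = hs$t, col = "firebrick", lty = 1)
  graphics::abline(v = to$t, col = "steelblue", lty = 2)
  invisible(x)
}

#' Detected events of a fit
#'
#' @param x a `gait_fit`.
#' @param ... unused.
#' @return The gait-event data frame.
#' @export
events <- function(x, ...) UseMethod("events")

#' @rdname events
#' @export
events.gait_fit <- function(x, ...) x$events

#' Run the pipeline on a CSV file and write outputs
#'
#' Reads the trace (and FSR channels when present), runs [gait_detect()],
#' writes the detected events to `events_out`, and - when FSR data are
#' present - an evaluation report to `report_out`. The calibration summary
#' is logged via [message()].
#'
#' @param trace_path input CSV path.
#' @param config a [gait_config()] list.
#' @param events_out path for the events CSV.
#' @param report_out path for the JSON report (only written when FSR
#'   channels exist).
#' @return The `gait_fit`, invisibly.
#' @export
run_pipeline <- function(trace_path, config = gait_config(),
                         events_out = "events.csv",
                         report_out = "report.json") {
  fit <- gait_detect(trace_path, config)
  message(sprintf("calibration: tau=%d event_scale=%d cycle_scale=%d, %d window events",
                  fit$calibration$scales$tau, fit$calibration$scales$mu_e_hat,
                  fit$calibration$scales$mu_c_hat, nrow(fit$calibration$events)))
  write_events_csv(fit$events, events_out)
  if (!is.null(fit$evaluation)) {
    acc <- fit$evaluation$accuracy
    rep <- list(
      accuracy = acc,
      timing = if (!is.null(fit$evaluation$timing)) {
        tw <- fit$evaluation$timing
        list(n = tw$n, MD = tw$MD, MD_sd = tw$MD_sd, AMD = tw$AMD,
             AMD_sd = tw$AMD_sd, loa = c(tw$loa_low, tw$loa_high),
             ci95 = tw$ci95)
      }
    )
    writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA),
               report_out)
  }
  invisible(fit)
}
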