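# Reference gait events from force-sensitive-resistor (FSR) foot switches.

#' Heel/toe FSR trace
#'
#' Stores the two insole channels after baseline removal (each channel has
#' its minimum subtracted, so values are non-negative in arbitrary sensor
#' units).
#'
#' @param heel,toe numeric force sequences of equal length.
#' @param fs sampling frequency (Hz).
#' @return An object of class `fsr_trace`.
#' @export
fsr_trace <- function(heel, toe, fs) {
  if (length(heel) != length(toe)) stop("heel and toe channels must have equal length")
  if (fs <= 0) stop("`fs` must be positive")
  structure(list(fs = fs, heel = as.numeric(heel) - min(heel),
                 toe = as.numeric(toe) - min(toe)),
            class = "fsr_trace")
}

#' @export
print.fsr_trace <- function(x, ...) {
  cat(sprintf("<fsr_trace: %d samples @ %.2f Hz>\n", length(x$heel), x$fs))
  invisible(x)
}

# First samples at/after upward (dir = +1) or downward (dir = -1) crossings
# of `thr`, with the crossing time linearly interpolated between samples.
threshold_crossings <- function(x, thr, fs, dir) {
  n <- length(x)
  if (n < 2L) return(data.frame(n = integer(0), t = numeric(0)))
  a <- x[-n]
  b <- x[-1L]
  hit <- if (dir > 0) a < thr & b >= thr else a > thr & b <= thr
  i <- which(hit)
  frac <- (thr - a[i]) / (b[i] - a[i])
  data.frame(n = i + 1L, t = (i - 1 + frac) / fs)
}

#' Extract reference gait events from FSR channels
#'
#' Per-channel amplitude references are the maxima over the observation
#' window. HS events are upward crossings of the heel channel through 5\% of
#' the heel reference; TO events are, by default, downward crossings of the
#' toe channel through 95\% of the toe reference (a 5\% decrease from the
#' maximum; `toe_rule = "below_5"` selects the alternative literal reading
#' of a drop below 5\% of the maximum). Each channel is debounced with a
#' refractory period of `0.25 x` its median inter-event interval.
#'
#' @param fsr an [fsr_trace()].
#' @param window integer pair `c(start, end)`: observation-window sample
#'   range used for the amplitude references; defaults to the whole trace.
#' @param toe_rule `"drop_from_max"` (default, 95\% crossing) or
#'   `"below_5"`.
#' @return A gait-event data frame (`kind`, `n`, `t`, `amplitude`), sorted
#'   by time.
#' @export
detect_fsr_events <- function(fsr, window = NULL,
                              toe_rule = c("drop_from_max", "below_5")) {
  stopifnot(inherits(fsr, "fsr_trace"))
  toe_rule <- match.arg(toe_rule)
  n <- length(fsr$heel)
  if (is.null(window)) window <- c(1L, n)
  win <- window[1L]:window[2L]
  heel_ref <- max(fsr$heel[win])
  toe_ref <- max(fsr$toe[win])
  if (heel_ref <= 0) stop("heel channel has zero amplitude in the window")
  if (toe_ref <= 0) stop("toe channel has zero amplitude in the window")
  hs_thr <- 0.05 * heel_ref
  to_thr <- if (toe_rule == "drop_from_max") 0.95 * toe_ref else 0.05 * toe_ref
  hs <- threshold_crossings(fsr$heel, hs_thr, fsr$fs, dir = +1)
  to <- threshold_crossings(fsr$toe, to_thr, fsr$fs, dir = -1)
  hs <- debounce_events(hs)
  to <- debounce_events(to)
  ev <- rbind(
    if (nrow(hs)) data.frame(kind = "HS", n = hs$n, t = hs$t,
                             amplitude = hs_thr, stringsAsFactors = FALSE),
    if (nrow(to)) data.frame(kind = "TO", n = to$n, t = to$t,
                             amplitude = to_thr, stringsAsFactors = FALSE)
  )
  if (is.null(ev) || !nrow(ev)) {
    return(data.frame(kind = character(0), n = integer(0), t = numeric(0),
                      amplitude = numeric(0), stringsAsFactors = FALSE))
  }
  ev <- ev[order(ev$t), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# Drop crossings closer than 0.25 x the median inter-event interval to the
# previously kept one (suppresses contact chatter around a threshold).
debounce_events <- function(ev) {
  if (nrow(ev) < 3L) return(ev)
  refractory <- 0.25 * stats::median(diff(ev$t))
  keep <- logical(nrow(ev))
  keep[1L] <- TRUE
  last_t <- ev$t[1L]
  for (i in 2:nrow(ev)) {
    if (ev$t[i] - last_t >= refractory) {
      keep[i] <- TRUE
      last_t <- ev$t[i]
    }
  }
  ev[keep, , drop = FALSE]
}
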