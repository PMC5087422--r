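# Synthetic gait trials with programmed ground truth. The generator
# emulates periodic walking as two damped-oscillation jerk bursts per gait
# cycle (heel strike and toe off) on a gravity baseline, with
# terrain-dependent burst amplitudes, cadence jitter, additive noise, and
# trapezoidal FSR contact pulses keyed to the same event times.

#' Gait simulation profile
#'
#' @param cadence stride rate in strides/s (default 0.9; one stride = one
#'   full gait cycle).
#' @param swing_frac fraction of the cycle spent in swing (default 0.38).
#' @param hs_amp,to_amp peak burst accelerations in g for heel-strike and
#'   toe-off bursts.
#' @param burst_freq frequency (Hz) of the damped oscillation inside a
#'   burst (default 8).
#' @param noise_sigma per-axis additive Gaussian noise SD in g
#'   (default 0.05).
#' @param cadence_jitter fractional SD of the per-cycle period
#'   (default 0.02).
#' @param lead_in seconds of quiet standing before walking (default 2).
#' @return An object of class `gait_profile`.
#' @export
gait_profile <- function(cadence = 0.9, swing_frac = 0.38,
                         hs_amp = 3.0, to_amp = 2.0, burst_freq = 8,
                         noise_sigma = 0.05, cadence_jitter = 0.02,
                         lead_in = 2) {
  if (cadence <= 0) stop("`cadence` must be positive")
  if (swing_frac <= 0 || swing_frac >= 1) stop("`swing_frac` must be in (0, 1)")
  if (hs_amp <= 0 || to_amp <= 0) stop("burst amplitudes must be positive")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (cadence_jitter < 0) stop("`cadence_jitter` must be >= 0")
  if (lead_in < 0) stop("`lead_in` must be >= 0")
  structure(list(cadence = cadence, swing_frac = swing_frac,
                 hs_amp = hs_amp, to_amp = to_amp, burst_freq = burst_freq,
                 noise_sigma = noise_sigma, cadence_jitter = cadence_jitter,
                 lead_in = lead_in),
            class = "gait_profile")
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf(
    "<gait_profile: %.2f strides/s, swing %.0f%%, HS/TO bursts %.1f/%.1f g, noise %.3f g>\n",
    x$cadence, 100 * x$swing_frac, x$hs_amp, x$to_amp, x$noise_sigma))
  invisible(x)
}

#' Terrain presets
#'
#' Three profiles emulating level-ground, up-stairs and down-stairs walking.
#' Stair cadences are slower than level ground and the burst amplitudes
#' differ by terrain (stair descent gives the hardest heel strikes, stair
#' ascent the gentlest), so no fixed amplitude threshold works across all
#' three - which is what the self-calibration is for.
#'
#' @return Named list of [gait_profile()] objects: `level`, `up`, `down`.
#' @export
terrain_presets <- function() {
  list(
    level = gait_profile(cadence = 0.90, hs_amp = 3.5, to_amp = 2.4),
    up    = gait_profile(cadence = 0.75, hs_amp = 2.8, to_amp = 2.3),
    down  = gait_profile(cadence = 0.80, hs_amp = 4.5, to_amp = 3.0)
  )
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Damped-sinusoid burst added in place along fixed direction cosines.
add_burst <- function(axes, t, te, amp, freq, dir, tau_d = 0.18,
                      support = 0.45) {
  idx <- which(t >= te & t <= te + support)
  if (!length(idx)) return(axes)
  u <- t[idx] - te
  b <- amp * sin(2 * pi * freq * u) * exp(-u / tau_d)
  axes$ax[idx] <- axes$ax[idx] + dir[1L] * b
  axes$ay[idx] <- axes$ay[idx] + dir[2L] * b
  axes$az[idx] <- axes$az[idx] + dir[3L] * b
  axes
}

# Trapezoidal pulse: ramp 0->amp over [t0, t0+rise], hold, ramp down to 0
# over [t1, t1+fall]. Added in place.
add_trapezoid <- function(sig, t, t0, rise, t1, fall, amp) {
  up <- t >= t0 & t < t0 + rise
  hold <- t >= t0 + rise & t < t1
  down <- t >= t1 & t <= t1 + fall
  sig[up] <- sig[up] + amp * (t[up] - t0) / rise
  sig[hold] <- sig[hold] + amp
  sig[down] <- sig[down] + amp * (1 - (t[down] - t1) / fall)
  sig
}

#' Generate one synthetic gait trial
#'
#' Quiet standing for `lead_in` seconds (gravity plus noise), then gait
#' cycles at a jittered cadence. Each cycle places an HS burst at the cycle
#' start and a TO burst at the end of stance
#' (`(1 - swing_frac) x` cycle period later); bursts are damped sinusoids
#' at `burst_freq` distributed over the three axes with fixed direction
#' cosines. FSR channels are trapezoids keyed to the same times: heel
#' loading starts at HS, and toe unloading completes at TO. Reproducible
#' for a given seed; the caller's RNG state is untouched.
#'
#' @param profile a [gait_profile()].
#' @param duration trial length in seconds (must cover `lead_in` plus at
#'   least two cycles).
#' @param seed integer random seed.
#' @param fs sampling frequency (Hz, default 148.15).
#' @return An object of class `synthetic_trial`: list with `accel`
#'   ([accel_trace()]), `fsr` ([fsr_trace()]), `truth` (gait-event data
#'   frame), `profile`, `seed`, `fs`, `duration`.
#' @export
generate_trial <- function(profile, duration = 12, seed = 1, fs = 148.15) {
  stopifnot(inherits(profile, "gait_profile"))
  period <- 1 / profile$cadence
  if (duration < profile$lead_in + 2 * period) {
    stop(sprintf("infeasible profile: duration %.1f s < lead-in %.1f s + 2 cycles (%.1f s)",
                 duration, profile$lead_in, 2 * period))
  }
  with_seed(seed, {
    n <- round(duration * fs)
    t <- (seq_len(n) - 1) / fs
    axes <- list(ax = numeric(n), ay = numeric(n), az = rep(1, n))
    heel <- numeric(n)
    toe <- numeric(n)

    hs_dir <- c(0.45, 0.25, 0.86)
    hs_dir <- hs_dir / sqrt(sum(hs_dir^2))
    to_dir <- c(0.65, 0.35, 0.67)
    to_dir <- to_dir / sqrt(sum(to_dir^2))

    truth_kind <- character(0)
    truth_t <- numeric(0)
    cyc_start <- profile$lead_in
    repeat {
      period_k <- period * max(0.5, 1 + profile$cadence_jitter * stats::rnorm(1))
      if (cyc_start + period_k > duration) break
      stance <- (1 - profile$swing_frac) * period_k
      t_hs <- cyc_start
      t_to <- cyc_start + stance
      axes <- add_burst(axes, t, t_hs, profile$hs_amp, profile$burst_freq,
                        hs_dir)
      axes <- add_burst(axes, t, t_to, profile$to_amp, profile$burst_freq,
                        to_dir)
      heel <- add_trapezoid(heel, t, t_hs, 0.05,
                            t_hs + 0.65 * stance, 0.05, 10)
      toe <- add_trapezoid(toe, t, t_hs + 0.30 * stance, 0.05,
                           t_to - 0.05, 0.05, 8)
      truth_kind <- c(truth_kind, "HS", "TO")
      truth_t <- c(truth_t, t_hs, t_to)
      cyc_start <- cyc_start + period_k
    }
    if (profile$noise_sigma > 0) {
      axes$ax <- axes$ax + stats::rnorm(n, sd = profile$noise_sigma)
      axes$ay <- axes$ay + stats::rnorm(n, sd = profile$noise_sigma)
      axes$az <- axes$az + stats::rnorm(n, sd = profile$noise_sigma)
    }
    truth <- data.frame(kind = truth_kind, n = round(truth_t * fs) + 1L,
                        t = truth_t, amplitude = NA_real_,
                        stringsAsFactors = FALSE)
    structure(
      list(accel = accel_trace(axes$ax, axes$ay, axes$az, fs = fs),
           fsr = fsr_trace(heel, toe, fs = fs),
           truth = truth, profile = profile, seed = seed, fs = fs,
           duration = duration),
      class = "synthetic_trial"
    )
  })
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial: %.1f s @ %.2f Hz, %d truth events, seed %d>\n",
              x$duration, x$fs, nrow(x$truth), x$seed))
  print(x$profile)
  invisible(x)
}

#' Write a synthetic trial to CSV
#'
#' Trace (plus FSR channels) goes to `path` in the [read_trace_csv()]
#' schema; ground-truth events go to `truth_path` (columns `kind, t_s`)
#' when given.
#'
#' @param trial a `synthetic_trial`.
#' @param path trace CSV path.
#' @param truth_path optional truth CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path, truth_path = NULL) {
  write_trace_csv(trial$accel, path, fsr = trial$fsr)
  if (!is.null(truth_path)) {
    utils::write.csv(data.frame(kind = trial$truth$kind,
                                t_s = trial$truth$t),
                     truth_path, row.names = FALSE)
  }
  invisible(path)
}
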