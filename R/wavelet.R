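# Morlet continuous wavelet transform and scale-domain calibration.
#
# Scales are expressed in samples, so the analysed frequency at scale s is
# f = fc * fs / s with fc the Morlet centre frequency. The integer grid
# 1..s_max is used throughout, matching how analysis scales are quoted for
# this detector (event scale 75, cycle scale 150, s_max 241 at fs = 148.15
# Hz, fc = 0.8125 Hz).

#' Morlet wavelet parameters
#'
#' The centre frequency `fc` fixes the dimensionless centre angular frequency
#' as `w0 = 2*pi*fc` (with the mother wavelet's argument in seconds), so the
#' frequency-scale map `f = fc*fs/s` is exact.
#'
#' @param fc centre frequency in Hz (default 0.8125).
#' @return A list with `fc` and `w0`.
#' @export
morlet_params <- function(fc = 0.8125) {
  if (fc <= 0) stop("`fc` must be positive")
  list(fc = fc, w0 = 2 * pi * fc)
}

#' Map a frequency to a wavelet scale
#'
#' `s = fc * fs / f`, rounded half-up to the integer scale grid.
#'
#' @param f frequency in Hz (> 0).
#' @param fc Morlet centre frequency in Hz.
#' @param fs sampling frequency in Hz.
#' @param round if `FALSE`, return the unrounded scale.
#' @return The scale (integer-valued unless `round = FALSE`).
#' @examples
#' scale_for_frequency(1.6)  # 75
#' scale_for_frequency(0.8)  # 150
#' scale_for_frequency(0.5)  # 241
#' @export
scale_for_frequency <- function(f, fc = 0.8125, fs = 148.15, round = TRUE) {
  if (any(f <= 0)) stop("`f` must be positive")
  s <- fc * fs / f
  if (round) round_half_up(s) else s
}

# Mother Morlet wavelet psi0(eta) = pi^(-1/4) exp(i w0 eta) exp(-eta^2/2).
morlet_psi <- function(eta, w0) {
  pi^(-1 / 4) * exp(1i * w0 * eta) * exp(-eta^2 / 2)
}

#' Morlet continuous wavelet transform
#'
#' Computes `W[s, n] = 1/sqrt(s) * sum_k x[k] * Conj(psi0((k - n)/s))` on an
#' integer scale grid with zero-padded boundaries. The `1/sqrt(s)`
#' normalisation gives comparable coefficient magnitudes across scales. The
#' kernel is truncated at `|eta| = 8`, beyond which the Gaussian envelope is
#' below 1.3e-14.
#'
#' @param x numeric signal or a [jerk_trace()].
#' @param scales integer vector of scales (samples), e.g. `1:241`.
#' @param params a [morlet_params()] list.
#' @return An object of class `scalogram`: list with complex matrix `W`
#'   (scales x time), `scales`, and `fs` when known.
#' @export
cwt_morlet <- function(x, scales, params = morlet_params()) {
  fs <- NA_real_
  if (inherits(x, "jerk_trace")) {
    fs <- x$fs
    x <- x$J
  }
  if (length(scales) == 0L) stop("`scales` must be non-empty")
  if (any(scales < 1)) stop("scales must be >= 1")
  n <- length(x)
  W <- matrix(0i, nrow = length(scales), ncol = n)
  for (i in seq_along(scales)) {
    s <- scales[i]
    h <- ceiling(8 * s)
    k <- (-h):h
    kern <- Conj(morlet_psi(k / s, params$w0)) / sqrt(s)
    W[i, ] <- correlate_kernel(x, kern, h)
  }
  structure(list(W = W, scales = as.integer(scales), fs = fs),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram: %d scales (%d..%d) x %d samples>\n",
              length(x$scales), min(x$scales), max(x$scales), ncol(x$W)))
  invisible(x)
}

#' Prior scale-energy spectrum
#'
#' Two-Gaussian mixture over the integer scale grid expressing the prior
#' belief that gait-event energy sits near scale `mu_e` and gait-cycle
#' energy near `mu_c`:
#' `E[s] = exp(-((s - mu_e)/sigma1)^2) + exp(-((s - mu_c)/sigma2)^2)`.
#'
#' @param s_max maximum scale (grid is `1:s_max`).
#' @param mu_e,mu_c prior event and cycle scales (defaults 75 and 150).
#' @param sigma1,sigma2 spread parameters (defaults 15 and 25).
#' @return Numeric vector of length `s_max`.
#' @export
prior_energy_spectrum <- function(s_max = 241, mu_e = 75, mu_c = 150,
                                  sigma1 = 15, sigma2 = 25) {
  if (any(c(s_max, mu_e, mu_c, sigma1, sigma2) <= 0)) {
    stop("all parameters must be positive")
  }
  if (!(mu_e < mu_c && mu_c <= s_max)) stop("need mu_e < mu_c <= s_max")
  s <- seq_len(s_max)
  exp(-((s - mu_e) / sigma1)^2) + exp(-((s - mu_c) / sigma2)^2)
}

#' Scale-dependent energy spectrum of a scalogram
#'
#' `E[s] = sum_n |W[s, n]|^2`.
#'
#' @param scal a `scalogram` from [cwt_morlet()].
#' @return Non-negative numeric vector, one entry per scale.
#' @export
energy_spectrum <- function(scal) {
  stopifnot(inherits(scal, "scalogram"))
  rowSums(Mod(scal$W)^2)
}

#' Scale delay between prior and observed energy spectra
#'
#' Both spectra are normalised to unit maximum, then linearly
#' cross-correlated (zero-padded) over the symmetric lag range
#' `[-(s_max-1), s_max-1]`. The returned lag maximises the correlation; a
#' positive value means the observed energy sits at larger scales (slower
#' gait) than the prior.
#'
#' @param e_prior,e_obs equal-length non-negative spectra.
#' @return Integer lag `tau`.
#' @export
scale_delay <- function(e_prior, e_obs) {
  s_max <- length(e_prior)
  if (length(e_obs) != s_max) stop("spectra must have equal length")
  if (max(e_obs) <= 0) stop("observed spectrum is all zero: calibration impossible")
  ep <- e_prior / max(e_prior)
  eo <- e_obs / max(e_obs)
  # conv(eo, rev(ep))[m] = sum_s ep[s] * eo[s + (m - s_max)]
  cc <- Re(conv_open(eo, rev(ep)))
  lag <- which.max(cc) - s_max
  as.integer(lag)
}

#' Split the spectrum and refine the event and cycle scales
#'
#' The valley `s_lambda` is the argmin of the observed spectrum over the
#' shifted prior interval `[mu_e + tau, mu_c + tau]` (clipped to the grid);
#' the posterior event scale is the argmax over `[1, s_lambda]` and the
#' posterior cycle scale the argmax over `[s_lambda, s_max]`. Ties break to
#' the smallest index.
#'
#' @param e_obs observed energy spectrum over scales `1:s_max`.
#' @param tau integer scale delay from [scale_delay()].
#' @param mu_e,mu_c prior event and cycle scales.
#' @return An object of class `scale_estimate`: list with `tau`, `s_lambda`,
#'   `mu_e_hat`, `mu_c_hat`.
#' @export
split_and_refine <- function(e_obs, tau, mu_e = 75, mu_c = 150) {
  s_max <- length(e_obs)
  lo <- max(1L, as.integer(mu_e + tau))
  hi <- min(s_max, as.integer(mu_c + tau))
  if (lo > hi) {
    stop(sprintf("shifted interval [%d, %d] empty after clipping to [1, %d]",
                 as.integer(mu_e + tau), as.integer(mu_c + tau), s_max))
  }
  s_lambda <- lo - 1L + which.min(e_obs[lo:hi])
  mu_e_hat <- which.max(e_obs[seq_len(s_lambda)])
  mu_c_hat <- s_lambda - 1L + which.max(e_obs[s_lambda:s_max])
  structure(list(tau = as.integer(tau), s_lambda = as.integer(s_lambda),
                 mu_e_hat = as.integer(mu_e_hat),
                 mu_c_hat = as.integer(mu_c_hat)),
            class = "scale_estimate")
}

#' @export
print.scale_estimate <- function(x, ...) {
  cat(sprintf(
    "<scale_estimate: tau = %d, split = %d, event scale = %d, cycle scale = %d>\n",
    x$tau, x$s_lambda, x$mu_e_hat, x$mu_c_hat))
  invisible(x)
}
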