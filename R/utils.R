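# Shared numeric helpers.

#' Round half away from zero to the nearest integer
#'
#' Unlike [base::round()], which rounds half to even, values ending in .5 are
#' always rounded up in magnitude. Used wherever an analysis scale is printed
#' as an integer.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Indices of local extrema
#'
#' A local maximum is a sample strictly greater than both neighbours; for a
#' plateau the first sample of the run is reported. Endpoints are never
#' extrema.
#'
#' @param x numeric vector.
#' @param what `"max"` or `"min"`.
#' @return integer vector of indices (possibly empty).
#' @keywords internal
local_extrema <- function(x, what = c("max", "min")) {
  what <- match.arg(what)
  if (what == "min") x <- -x
  if (length(x) < 3L) return(integer(0))
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  v <- r$values
  mid <- which(v[2:(k - 1L)] > v[1:(k - 2L)] & v[2:(k - 1L)] > v[3:k]) + 1L
  starts[mid]
}

# Linear ("open") convolution via FFT; inputs may be complex.
conv_open <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  m <- stats::nextn(na + nb - 1L, 2L)
  pa <- c(a, rep(0, m - na))
  pb <- c(b, rep(0, m - nb))
  res <- stats::fft(stats::fft(pa) * stats::fft(pb), inverse = TRUE) / m
  res[seq_len(na + nb - 1L)]
}

# Zero-padded cross-correlation of a real signal with a complex kernel
# defined on offsets -h..h: y[n] = sum_k x[n + k] * kern[k + h + 1].
correlate_kernel <- function(x, kern, h) {
  n <- length(x)
  full <- conv_open(as.complex(x), rev(kern))
  full[seq_len(n) + h]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Zero-phase (forward-backward) IIR filtering with odd-reflection padding
# and steady-state initial conditions, so a constant input produces the
# filter's exact DC response with no startup transient.
filtfilt_ss <- function(bf, x) {
  b <- bf$b
  a <- bf$a
  nf <- 3L * (max(length(a), length(b)) - 1L)
  n <- length(x)
  if (n <= nf + 1L) {
    stop(sprintf("signal too short for zero-phase filtering: need more than %d samples", nf + 1L))
  }
  pre <- 2 * x[1L] - x[(nf + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - nf)]
  xe <- c(pre, x, post)
  h1 <- sum(b) / sum(a)
  pass <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1L], length(b) - 1L),
                              init.y = rep(z[1L] * h1, length(a) - 1L)))
  }
  y <- rev(pass(rev(pass(xe))))
  y[(nf + 1L):(nf + n)]
}
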