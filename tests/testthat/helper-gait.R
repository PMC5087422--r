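# Shared fixtures and independent oracles.

FS <- 148.15

# Threshold set built directly (bypasses window calibration) for detector
# unit tests where the gates must be controlled exactly.
make_thresholds <- function(TH2 = 1, TH3 = 4, TH4 = 3, T_swin = 0.4,
                            T_std = 0.6, r_b = 0.8, r1 = 0.5, r2 = 0.5) {
  structure(list(TH2 = TH2, TH3 = TH3, TH4 = TH4, T_swin = T_swin,
                 T_std = T_std, r_b = r_b, r1 = r1, r2 = r2),
            class = "threshold_set")
}

last_event_at <- function(kind = "TO", t = 0) {
  data.frame(kind = kind, n = round(t * FS) + 1L, t = t, amplitude = 1,
             stringsAsFactors = FALSE)
}

# Noiseless / noisy trial factories with a per-session cache, since several
# files reuse the same trials.
.trial_cache <- new.env(parent = emptyenv())
cached_trial <- function(terrain = "level", seed = 1, noise = NULL,
                         duration = 12) {
  key <- paste(terrain, seed, noise %||% "default", duration, sep = "_")
  if (is.null(.trial_cache[[key]])) {
    p <- terrain_presets()[[terrain]]
    if (!is.null(noise)) p$noise_sigma <- noise
    .trial_cache[[key]] <- generate_trial(p, duration = duration, seed = seed)
  }
  .trial_cache[[key]]
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force dense evaluation of the wavelet transform definition:
# W[s, n] = 1/sqrt(s) * sum_k x[k] Conj(psi0((k - n)/s)).
cwt_oracle <- function(x, scales, fc = 0.8125) {
  w0 <- 2 * pi * fc
  psi0 <- function(eta) pi^(-1 / 4) * exp(1i * w0 * eta) * exp(-eta^2 / 2)
  n <- length(x)
  W <- matrix(0i, length(scales), n)
  for (i in seq_along(scales)) {
    s <- scales[i]
    for (j in seq_len(n)) {
      eta <- ((seq_len(n) - j)) / s
      W[i, j] <- sum(x * Conj(psi0(eta))) / sqrt(s)
    }
  }
  W
}

# Exhaustive optimal one-to-one assignment: maximum number of same-kind
# pairs within tolerance (for <= 8 events per side).
match_count_oracle <- function(detected, reference, tolerance) {
  nd <- nrow(detected)
  best <- 0L
  recurse <- function(d, used_r, count) {
    if (count + (nd - d + 1L) <= best) return(invisible())
    if (d > nd) {
      best <<- max(best, count)
      return(invisible())
    }
    recurse(d + 1L, used_r, count) # leave d unmatched
    for (r in seq_len(nrow(reference))) {
      if (!used_r[r] &&
          reference$kind[r] == detected$kind[d] &&
          abs(reference$t[r] - detected$t[d]) <= tolerance) {
        used_r[r] <- TRUE
        recurse(d + 1L, used_r, count + 1L)
        used_r[r] <- FALSE
      }
    }
  }
  if (nd) recurse(1L, logical(nrow(reference)), 0L) else best <- 0L
  best
}

random_events <- function(n, kinds = c("HS", "TO"), tmax = 10, seed = 1) {
  set.seed(seed)
  t <- sort(runif(n, 0, tmax))
  data.frame(kind = sample(kinds, n, replace = TRUE), n = round(t * FS) + 1L,
             t = t, amplitude = runif(n, 1, 5), stringsAsFactors = FALSE)
}
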