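# Accuracy (precision / recall / F1) and timing agreement (Bland-Altman)
# of a detected event stream against a reference stream.

#' Match detected events to reference events
#'
#' Greedy nearest-in-time one-to-one matching: candidate pairs of the same
#' kind within `tolerance` seconds are sorted by absolute time difference
#' and accepted while both members are unused. Matched pairs are true
#' positives; unmatched detected events are false positives and unmatched
#' reference events false negatives.
#'
#' @param detected,reference gait-event data frames (`kind`, `t`),
#'   time-sorted.
#' @param tolerance matching tolerance in seconds (default 0.4).
#' @return An object of class `match_result`: `pairs` (data frame with
#'   `det`, `ref` row indices and `diff_ms = (t_det - t_ref) * 1000`),
#'   `counts` (TP/FP/FN per kind and pooled), `tolerance`.
#' @export
match_events <- function(detected, reference, tolerance = 0.4) {
  nd <- nrow(detected)
  nr <- nrow(reference)
  cand <- NULL
  if (nd && nr) {
    grid <- expand.grid(det = seq_len(nd), ref = seq_len(nr))
    dt <- detected$t[grid$det] - reference$t[grid$ref]
    ok <- abs(dt) <= tolerance &
      detected$kind[grid$det] == reference$kind[grid$ref]
    cand <- data.frame(det = grid$det[ok], ref = grid$ref[ok],
                       diff_ms = dt[ok] * 1000)
    cand <- cand[order(abs(cand$diff_ms)), , drop = FALSE]
  }
  used_d <- logical(nd)
  used_r <- logical(nr)
  keep <- integer(0)
  if (!is.null(cand) && nrow(cand)) {
    for (i in seq_len(nrow(cand))) {
      d <- cand$det[i]
      r <- cand$ref[i]
      if (!used_d[d] && !used_r[r]) {
        used_d[d] <- TRUE
        used_r[r] <- TRUE
        keep <- c(keep, i)
      }
    }
  }
  pairs <- if (length(keep)) cand[keep, , drop = FALSE] else
    data.frame(det = integer(0), ref = integer(0), diff_ms = numeric(0))
  rownames(pairs) <- NULL
  kinds <- c("HS", "TO")
  counts <- lapply(kinds, function(k) {
    dk <- detected$kind == k
    rk <- reference$kind == k
    tp <- sum(dk[pairs$det])
    c(TP = tp, FP = sum(dk) - tp, FN = sum(rk) - sum(rk[pairs$ref]))
  })
  names(counts) <- kinds
  counts$pooled <- counts$HS + counts$TO
  structure(list(pairs = pairs, counts = counts, tolerance = tolerance),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: tolerance %.0f ms>\n", x$tolerance * 1000))
  for (k in names(x$counts)) {
    cat(sprintf("  %-6s TP=%d FP=%d FN=%d\n", k,
                x$counts[[k]]["TP"], x$counts[[k]]["FP"], x$counts[[k]]["FN"]))
  }
  invisible(x)
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, with the
#' zero-denominator convention that an undefined quantity is 0.
#'
#' @param TP,FP,FN non-negative counts.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @examples
#' prf1(18, 0, 2)  # F1 = 0.947 -> 0.95 at two decimals
#' @export
prf1 <- function(TP, FP, FN) {
  if (any(c(TP, FP, FN) < 0)) stop("counts must be non-negative")
  TP <- unname(TP); FP <- unname(FP); FN <- unname(FN)
  p <- if (TP + FP > 0) TP / (TP + FP) else 0
  r <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Accuracy report (per kind and pooled)
#'
#' @param match a `match_result`.
#' @return Data frame of class `accuracy_report` with rows HS, TO, pooled
#'   and columns `TP`, `FP`, `FN`, `precision`, `recall`, `f1`.
#' @export
accuracy_report <- function(match) {
  stopifnot(inherits(match, "match_result"))
  rows <- lapply(names(match$counts), function(k) {
    cnt <- match$counts[[k]]
    m <- prf1(cnt["TP"], cnt["FP"], cnt["FN"])
    data.frame(kind = k, TP = cnt[["TP"]], FP = cnt[["FP"]], FN = cnt[["FN"]],
               precision = m[["precision"]], recall = m[["recall"]],
               f1 = m[["f1"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' Timing agreement between matched event streams
#'
#' Bland-Altman style summary of the per-pair time differences
#' `(t_detected - t_reference)` in milliseconds: mean difference (MD) and
#' its SD, absolute mean difference (AMD) and its SD, limits of agreement
#' `MD +- 1.96 SD`, and the normal-theory 95\% CI of the mean
#' `MD +- 1.96 SD / sqrt(n)`.
#'
#' @param match a `match_result` with at least 2 pairs, or a numeric vector
#'   of differences in ms.
#' @param ba_means optional pairwise means for the Bland-Altman x axis (s);
#'   computed from event times when a `match_result` carries them.
#' @return An object of class `timing_report`.
#' @export
timing_agreement <- function(match, ba_means = NULL) {
  if (inherits(match, "match_result")) {
    diffs <- match$pairs$diff_ms
  } else {
    diffs <- as.numeric(match)
  }
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 matched pairs for timing agreement")
  md <- mean(diffs)
  sd_ <- stats::sd(diffs)
  amd <- mean(abs(diffs))
  amd_sd <- stats::sd(abs(diffs))
  structure(
    list(diffs = diffs, n = n,
         MD = md, MD_sd = sd_, AMD = amd, AMD_sd = amd_sd,
         loa_low = md - 1.96 * sd_, loa_high = md + 1.96 * sd_,
         ci95 = c(md - 1.96 * sd_ / sqrt(n), md + 1.96 * sd_ / sqrt(n)),
         ba_means = ba_means),
    class = "timing_report"
  )
}

#' @export
print.timing_report <- function(x, ...) {
  cat("<timing_report>\n")
  cat(sprintf("  n pairs : %d\n", x$n))
  cat(sprintf("  MD      : %.1f +/- %.1f ms\n", x$MD, x$MD_sd))
  cat(sprintf("  AMD     : %.1f +/- %.1f ms\n", x$AMD, x$AMD_sd))
  cat(sprintf("  LoA     : [%.1f, %.1f] ms\n", x$loa_low, x$loa_high))
  cat(sprintf("  95%% CI  : [%.1f, %.1f] ms\n", x$ci95[1L], x$ci95[2L]))
  invisible(x)
}

#' Bland-Altman plot of a timing report
#'
#' @param x a `timing_report` with `ba_means` set.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.timing_report <- function(x, ...) {
  xs <- x$ba_means %||% seq_along(x$diffs)
  graphics::plot(xs, x$diffs,
                 xlab = if (is.null(x$ba_means)) "pair index" else
                   "pairwise mean time (s)",
                 ylab = "time difference (ms)", ...)
  graphics::abline(h = c(x$MD, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}

#' Evaluate a detected event stream against a reference
#'
#' Convenience wrapper: optionally trims the final gait cycle (events at or
#' after the last reference HS are dropped from both streams, since a
#' truncated final cycle is not scoreable), matches, and computes accuracy
#' and timing agreement.
#'
#' @param detected,reference gait-event data frames.
#' @param tolerance matching tolerance (s).
#' @param exclude_last_cycle drop the final reference gait cycle before
#'   scoring (default `TRUE`).
#' @return An object of class `gait_evaluation`: list with `match`,
#'   `accuracy`, and `timing` (`NULL` when fewer than 2 pairs).
#' @export
evaluate_events <- function(detected, reference, tolerance = 0.4,
                            exclude_last_cycle = TRUE) {
  if (exclude_last_cycle) {
    hs_t <- reference$t[reference$kind == "HS"]
    if (length(hs_t) >= 2L) {
      cut <- max(hs_t)
      detected <- detected[detected$t < cut, , drop = FALSE]
      reference <- reference[reference$t < cut, , drop = FALSE]
    }
  }
  match <- match_events(detected, reference, tolerance)
  ba <- NULL
  if (nrow(match$pairs) >= 2L) {
    ba_means <- (detected$t[match$pairs$det] +
                   reference$t[match$pairs$ref]) / 2
    ba <- timing_agreement(match, ba_means = ba_means)
  }
  structure(list(match = match, accuracy = accuracy_report(match),
                 timing = ba),
            class = "gait_evaluation")
}

#' @export
print.gait_evaluation <- function(x, ...) {
  cat("<gait_evaluation>\n")
  print.data.frame(x$accuracy, digits = 3)
  if (!is.null(x$timing)) print(x$timing)
  invisible(x)
}
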