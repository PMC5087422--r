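# Corpus-level evaluation utilities.

#' Run the full pipeline over a synthetic corpus
#'
#' Generates seeded trials for each terrain preset, runs preprocessing,
#' window calibration and the streaming detector, and scores the detected
#' events against the simulator's ground truth (final gait cycle excluded).
#'
#' @param seeds integer vector of trial seeds (used for every terrain).
#' @param duration trial length in seconds (default 12).
#' @param noise_sigma per-axis acceleration noise SD in g (default 0.05).
#' @param config a [gait_config()] list.
#' @param terrains subset of `names(terrain_presets())`.
#' @return Data frame with one row per trial: `terrain`, `seed`, `f1_hs`,
#'   `f1_to`, `f1_pooled`, `n_truth`, `n_detected`. A trial whose
#'   calibration fails scores 0 (with a warning).
#' @export
benchmark_corpus <- function(seeds = 1:10, duration = 12, noise_sigma = 0.05,
                             config = gait_config(),
                             terrains = names(terrain_presets())) {
  presets <- terrain_presets()[terrains]
  rows <- list()
  for (terr in names(presets)) {
    p <- presets[[terr]]
    p$noise_sigma <- noise_sigma
    for (s in seeds) {
      trial <- generate_trial(p, duration = duration, seed = s)
      fit <- tryCatch(gait_detect(trial, config), error = function(e) e)
      if (inherits(fit, "error")) {
        warning(sprintf("trial %s/%d failed: %s", terr, s,
                        conditionMessage(fit)))
        f1 <- c(0, 0, 0)
        nd <- 0L
      } else {
        acc <- fit$truth_evaluation$accuracy
        f1 <- acc$f1[match(c("HS", "TO", "pooled"), acc$kind)]
        nd <- nrow(fit$events)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        terrain = terr, seed = s, f1_hs = f1[1L], f1_to = f1[2L],
        f1_pooled = f1[3L], n_truth = nrow(trial$truth), n_detected = nd,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep the membership parameters r1 and r2
#'
#' Re-runs the synthetic corpus for every combination of the two stride
#' membership fractions and reports the mean pooled F1, the procedure used
#' to justify the default `r1 = r2 = 0.5`.
#'
#' @param r1_grid,r2_grid numeric grids in (0, 1] (default
#'   `c(0.1, 0.3, 0.5, 0.7, 0.9)`).
#' @param seeds trial seeds per terrain (default `1:3`).
#' @param ... passed to [benchmark_corpus()].
#' @return Data frame with `r1`, `r2`, `mean_f1`.
#' @export
sweep_memberships <- function(r1_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                              r2_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                              seeds = 1:3, ...) {
  grid <- expand.grid(r1 = r1_grid, r2 = r2_grid)
  grid$mean_f1 <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- gait_config(r1 = grid$r1[i], r2 = grid$r2[i])
    mean(benchmark_corpus(seeds = seeds, config = cfg, ...)$f1_pooled)
  }, numeric(1))
  grid
}
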