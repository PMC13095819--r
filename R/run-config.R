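#' Pipeline run configuration
#'
#' Aggregates every numeric protocol constant of the decoding pipeline in
#' one validated object: the analysis band, calibration windowing, the
#' closed-loop update step, the epoch span, the spectral baseline, the fold
#' rule and the competence-gate threshold. The defaults are the protocol's
#' operating values.
#'
#' @param band Band-pass interval, Hz (default `c(8, 30)`).
#' @param window Window length, s (default 2).
#' @param overlap Calibration window overlap (default 0.5).
#' @param step Closed-loop decision period, s (default 0.0625, i.e. 16
#'   decisions/s).
#' @param epoch_span Post-cue epoch, s (default `c(1, 6)`).
#' @param baseline Spectral reference interval, s (default `c(-1, 0)`).
#' @param k Cross-validation folds, `"auto"` = run count.
#' @param threshold Competence-gate threshold (default 0.70).
#' @param seed Integer seed.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(band = c(8, 30), window = 2, overlap = 0.5,
                       step = 0.0625, epoch_span = c(1, 6),
                       baseline = c(-1, 0), k = "auto", threshold = 0.70,
                       seed = 1) {
  assert_that(band[1] > 0 && band[1] < band[2], "band must be increasing and positive")
  assert_that(window > 0 && step > 0 && overlap >= 0 && overlap < 1,
              "window/step/overlap out of range")
  assert_that(epoch_span[2] - epoch_span[1] >= window, "epoch span shorter than window")
  assert_that(threshold > 0 && threshold <= 1, "threshold must lie in (0, 1]")
  structure(list(band = band, window = window, overlap = overlap, step = step,
                 epoch_span = epoch_span, baseline = baseline, k = k,
                 threshold = threshold, seed = as.integer(seed)),
            class = "run_config")
}

#' Save / load a run configuration (lossless JSON round-trip)
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `load_run_config` returns the `run_config`; `save_run_config`
#'   returns `path` invisibly.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, p)
}
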