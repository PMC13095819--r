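#' Labeled window set
#'
#' Fixed-length EEG windows with class labels and trial/run provenance —
#' the decoder's training currency. Stored as an `n x channels x samples`
#' array plus parallel `labels`, `trial_id` and `run_id` vectors.
#'
#' @param windows Numeric array `n x channels x samples`.
#' @param labels Character/factor, one class per window.
#' @param trial_id,run_id Integer provenance per window.
#' @param window_length,step Seconds.
#' @param sfreq Sampling rate, Hz.
#' @param channel_names Channel labels (length = dim 2).
#' @return Object of class `labeled_windows`.
#' @export
labeled_windows <- function(windows, labels, trial_id, run_id,
                            window_length, step, sfreq, channel_names) {
  n <- dim(windows)[1]
  assert_that(length(dim(windows)) == 3, "windows must be a 3-d array")
  assert_that(all(lengths(list(labels, trial_id, run_id)) == n),
              "labels/trial_id/run_id must match the number of windows")
  assert_that(dim(windows)[2] == length(channel_names),
              "second array dimension must match channel_names")
  structure(list(windows = windows, labels = as.character(labels),
                 trial_id = as.integer(trial_id), run_id = as.integer(run_id),
                 window_length = window_length, step = step, sfreq = sfreq,
                 channel_names = as.character(channel_names)),
            class = "labeled_windows")
}

#' @export
print.labeled_windows <- function(x, ...) {
  cat(sprintf("<labeled_windows> %d windows x %d ch x %d samples (%g s / step %g s)\n",
              dim(x$windows)[1], dim(x$windows)[2], dim(x$windows)[3],
              x$window_length, x$step))
  print(table(x$labels))
  invisible(x)
}

# Keep a subset of windows, preserving order. Removal only, never edits.
ws_subset <- function(ws, idx) {
  labeled_windows(ws$windows[idx, , , drop = FALSE], ws$labels[idx],
                  ws$trial_id[idx], ws$run_id[idx],
                  ws$window_length, ws$step, ws$sfreq, ws$channel_names)
}

#' Number of windows
#' @param ws A [labeled_windows()] set.
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$windows)[1]

# -- FIR band-pass ------------------------------------------------------------

# Hamming windowed-sinc band-pass taps; order from a ~2 Hz transition width.
design_bandpass <- function(low, high, sfreq, transition = 2) {
  order <- ceiling(3.3 * sfreq / transition)
  if (order %% 2 == 1) order <- order + 1  # type-I linear phase
  signal::fir1(order, c(low, high) / (sfreq / 2), type = "pass")
}

# Zero-lag FIR by forward FFT convolution with reflection padding and
# group-delay compensation (kernel must be odd-length symmetric).
apply_fir_zerolag <- function(x, h) {
  n <- length(x)
  m <- length(h)
  pad <- m  # reflection padding against edge transients
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  nf <- stats::nextn(length(xp) + m - 1, 2)
  y <- Re(stats::fft(stats::fft(c(xp, rep(0, nf - length(xp)))) *
                     stats::fft(c(h, rep(0, nf - m))), inverse = TRUE)) / nf
  delay <- (m - 1) / 2
  y[(pad + delay + 1):(pad + delay + n)]
}

# Causal (forward-only) FIR over the whole signal: sample t of the output
# depends only on inputs <= t. Used by the streaming decoder.
apply_fir_causal <- function(x, h) {
  n <- length(x)
  m <- length(h)
  nf <- stats::nextn(n + m - 1, 2)
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nf - n))) *
                     stats::fft(c(h, rep(0, nf - m))), inverse = TRUE)) / nf
  y[seq_len(n)]
}

#' Zero-lag FIR band-pass filter of a recording
#'
#' Hamming windowed-sinc finite-impulse-response filter retaining `low`-`high`
#' Hz (default 8-30 Hz, the mu + beta range that modulates during motor
#' imagery). The filter order follows from a ~2 Hz transition width; output is
#' linear-phase with the group delay compensated, so features stay aligned
#' with the annotations. Edges are handled by reflection padding.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz; `0 < low < high < sfreq / 2`.
#' @return A filtered [eeg_recording()] of identical shape.
#' @export
bandpass_fir <- function(rec, low = 8, high = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_that(low > 0 && low < high && high < rec$sfreq / 2,
              "band must satisfy 0 < low < high < Nyquist")
  h <- design_bandpass(low, high, rec$sfreq)
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    out$data[ch, ] <- apply_fir_zerolag(rec$data[ch, ], h)
  }
  out
}

# -- Epoching and windowing ---------------------------------------------------

#' Epoch annotated trials and cut sliding windows
#'
#' Extracts, for every annotated trial, the post-cue span
#' `[cue + epoch_span[1], cue + epoch_span[2])` and segments it with a sliding
#' window (default 2 s, 50% overlap), so the default 1-6 s span yields windows
#' starting at cue + 1, 2, 3 and 4 s. Labels are inherited from the trial cue
#' and `run_id` from the annotation's `run` column (series index).
#'
#' @param rec A (typically band-pass filtered) [eeg_recording()].
#' @param annotations Data frame `onset`/`duration`/`label` (+ optional
#'   `run`); defaults to `rec$annotations`.
#' @param epoch_span Length-2 numeric, seconds after the cue (default
#'   `c(1, 6)`).
#' @param window Window length, s (default 2).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @return A [labeled_windows()] set. Trials extending past the end of the
#'   recording are skipped with a warning.
#' @export
epoch_and_window <- function(rec, annotations = NULL, epoch_span = c(1, 6),
                             window = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  ann <- annotations %||% rec$annotations
  assert_that(nrow(ann) > 0, "no annotations to epoch")
  assert_that(epoch_span[2] - epoch_span[1] >= window,
              "epoch span must be at least one window long")
  step <- window * (1 - overlap)
  sf <- rec$sfreq
  run <- if ("run" %in% names(ann)) as.integer(ann$run) else rep(1L, nrow(ann))
  starts_rel <- seq(epoch_span[1], epoch_span[2] - window + 1e-9, by = step)
  wlen <- round(window * sf)
  dur <- rec_duration(rec)

  keep <- ann$onset + epoch_span[2] <= dur + 1e-9
  if (any(!keep)) {
    warning(sprintf("skipping %d truncated trial(s) that do not contain the %g-%g s epoch",
                    sum(!keep), epoch_span[1], epoch_span[2]))
  }
  idx <- which(keep)
  n_out <- length(idx) * length(starts_rel)
  win <- array(0, dim = c(n_out, nrow(rec$data), wlen))
  labels <- character(n_out); trial_id <- integer(n_out); run_id <- integer(n_out)
  k <- 0
  for (i in idx) {
    for (s0 in starts_rel) {
      k <- k + 1
      a <- round((ann$onset[i] + s0) * sf) + 1
      win[k, , ] <- rec$data[, a:(a + wlen - 1)]
      labels[k] <- ann$label[i]
      trial_id[k] <- i
      run_id[k] <- run[i]
    }
  }
  labeled_windows(win, labels, trial_id, run_id, window, step, sf,
                  rec$channel_names)
}

# -- Outlier-window rejection -------------------------------------------------

#' Reject outlier windows by robust log-variance z-scores
#'
#' Calibration-time artifact screening: within each class and channel the
#' log-variance of every window is converted to a robust z-score
#' (median/MAD-based; MAD scaled by 1.4826). A window is rejected when its
#' maximum |z| across channels exceeds `z_max`. This simple statistic is a
#' documented, pluggable stand-in for class-wise outlier screening — it is
#' deliberately conservative and is applied only to calibration data, never
#' in the closed loop. When the MAD of a channel is zero the standard
#' deviation is used instead; when that is also zero nothing is rejected on
#' that channel.
#'
#' @param ws A [labeled_windows()] set with at least 2 windows per class.
#' @param z_max Rejection threshold (default 3.5). `Inf` disables rejection.
#' @return A list: `windows` (the cleaned [labeled_windows()]), `report`
#'   (data frame of per-window max |z| and rejection flag), `rejected`
#'   (indices into the input).
#' @export
reject_outlier_windows <- function(ws, z_max = 3.5) {
  stopifnot(inherits(ws, "labeled_windows"))
  classes <- unique(ws$labels)
  assert_that(all(table(ws$labels) >= 2), "need at least 2 windows per class")
  n <- n_windows(ws)
  # log-variance per window x channel
  lv <- log(pmax(apply(ws$windows, c(1, 2), stats::var), 1e-300))
  score <- numeric(n)
  for (cl in classes) {
    rows <- which(ws$labels == cl)
    for (ch in seq_len(dim(ws$windows)[2])) {
      v <- lv[rows, ch]
      med <- stats::median(v)
      s <- stats::mad(v)            # 1.4826 * MAD
      if (s == 0) s <- stats::sd(v)
      z <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - med) / s
      score[rows] <- pmax(score[rows], abs(z))
    }
  }
  rejected <- which(score > z_max)
  for (cl in classes) {
    left <- sum(ws$labels[setdiff(seq_len(n), rejected)] == cl)
    if (left < 2) {
      stop2(sprintf("rejection left class '%s' with %d window(s); relax z_max (currently %g)",
                    cl, left, z_max))
    }
  }
  keep <- setdiff(seq_len(n), rejected)
  list(windows = ws_subset(ws, keep),
       report = data.frame(window = seq_len(n), label = ws$labels,
                           max_abs_z = score, rejected = seq_len(n) %in% rejected),
       rejected = rejected)
}
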