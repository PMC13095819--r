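#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the standard symmetric tridiagonal eigenproblem whose
#' eigenvectors are the Slepian sequences. Tapers are unit-energy;
#' signs follow the usual convention (even-order tapers have positive mean,
#' odd-order tapers a positive initial lobe).
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 2).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return An `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 2, k = 2 * nw - 1) {
  assert_that(k >= 1 && k < n, "need 1 <= k < n tapers")
  w <- nw / n
  t0 <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  diag_off <- (t0 * (n - t0) / 2)[-1]
  M <- diag(diag_main)
  M[cbind(2:n, 1:(n - 1))] <- diag_off
  M[cbind(1:(n - 1), 2:n)] <- diag_off
  e <- eigen(M, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- V[, j]
    v <- v / sqrt(sum(v^2))
    if (j %% 2 == 1) {
      if (sum(v) < 0) v <- -v          # even-order taper: positive mean
    } else {
      if (sum(v[seq_len(n %/% 2)]) < 0) v <- -v  # odd order: positive first lobe
    }
    V[, j] <- v
  }
  V
}

# Multitaper power spectrum of one signal segment: mean over tapers of the
# squared taper-windowed FFT. Returns power at the one-sided frequency grid.
multitaper_psd <- function(x, tapers) {
  n <- length(x)
  P <- 0
  for (j in seq_len(ncol(tapers))) {
    P <- P + Mod(stats::fft(x * tapers[, j]))^2
  }
  (P / ncol(tapers))[seq_len(n %/% 2 + 1)]
}

#' ERD/ERS time-frequency map
#'
#' Event-related (de)synchronization mapping of one task: for every trial an
#' EEG segment spanning `epoch` around the cue is cut, a DPSS multitaper
#' sliding-window spectrogram is computed per channel, spectrograms are
#' averaged over trials, and the average is expressed as percent change from
#' the pre-cue baseline: `100 * (P - B) / B`, where `B` is the mean power
#' over the baseline interval per channel and frequency. Averaging precedes
#' normalization (the average is normalized, not the normalized maps
#' averaged). Rows with zero baseline power are masked `NA` rather than
#' returning infinities.
#'
#' Spectrogram parameters (0.5-s windows, 50% overlap, time-bandwidth 2,
#' 3 tapers) resolve ~2 Hz structure across the 7-s epoch; the frequency
#' axis is restricted to 4-40 Hz.
#'
#' @param rec An [eeg_recording()] (raw, not band-pass filtered: the map
#'   itself is broadband).
#' @param annotations Optional annotation data frame (default
#'   `rec$annotations`).
#' @param task Task label to map (needs >= 5 usable trials).
#' @param channels Channel labels (default `c("C3", "Cz", "C4")`).
#' @param epoch Seconds around the cue (default `c(-1, 6)`).
#' @param baseline Reference interval, s (default `c(-1, 0)`).
#' @param spec_window,spec_overlap Spectrogram window length (s) and
#'   fractional overlap.
#' @param nw,k_tapers DPSS time-bandwidth product and taper count.
#' @param freq_range Hz limits of the returned map.
#' @return Object of class `tf_map`: `values` (channels x frequencies x
#'   times, percent change), `freq_axis`, `time_axis` (window centers,
#'   s relative to cue), `baseline_interval`, `channel_names`, `n_trials`.
#' @export
compute_erd_map <- function(rec, annotations = NULL, task,
                            channels = c("C3", "Cz", "C4"),
                            epoch = c(-1, 6), baseline = c(-1, 0),
                            spec_window = 0.5, spec_overlap = 0.5,
                            nw = 2, k_tapers = 3, freq_range = c(4, 40)) {
  stopifnot(inherits(rec, "eeg_recording"))
  ann <- annotations %||% rec$annotations
  ann <- ann[ann$label == task, , drop = FALSE]
  assert_that(nrow(ann) > 0, paste0("no trials with label '", task, "'"))
  assert_that(all(channels %in% rec$channel_names),
              "requested channels not in the recording")
  sf <- rec$sfreq
  dur <- rec_duration(rec)
  ok <- ann$onset + epoch[1] >= 0 & ann$onset + epoch[2] <= dur + 1e-9
  if (any(!ok)) {
    warning(sprintf("skipping %d trial(s) without the full %g-%g s span",
                    sum(!ok), epoch[1], epoch[2]))
  }
  ann <- ann[ok, , drop = FALSE]
  assert_that(nrow(ann) >= 5, "need at least 5 trials containing the epoch span")

  wlen <- round(spec_window * sf)
  step <- round(wlen * (1 - spec_overlap))
  seg_len <- round((epoch[2] - epoch[1]) * sf)
  starts <- seq(1, seg_len - wlen + 1, by = step)
  centers <- epoch[1] + (starts - 1 + wlen / 2) / sf
  tapers <- dpss_tapers(wlen, nw, k_tapers)
  freqs <- (seq_len(wlen %/% 2 + 1) - 1) * sf / wlen
  fsel <- which(freqs >= freq_range[1] & freqs <= freq_range[2])

  chi <- match(channels, rec$channel_names)
  P <- array(0, dim = c(length(channels), length(fsel), length(starts)))
  for (i in seq_len(nrow(ann))) {
    a0 <- round((ann$onset[i] + epoch[1]) * sf) + 1
    seg <- rec$data[chi, a0:(a0 + seg_len - 1), drop = FALSE]
    for (c in seq_along(chi)) {
      for (j in seq_along(starts)) {
        x <- seg[c, starts[j]:(starts[j] + wlen - 1)]
        P[c, , j] <- P[c, , j] + multitaper_psd(x, tapers)[fsel]
      }
    }
  }
  P <- P / nrow(ann)

  base_cols <- which(centers - spec_window / 2 >= baseline[1] - 1e-9 &
                     centers + spec_window / 2 <= baseline[2] + 1e-9)
  assert_that(length(base_cols) > 0, "no spectrogram window fits the baseline interval")
  vals <- P
  for (c in seq_along(chi)) {
    for (fi in seq_along(fsel)) {
      b <- mean(P[c, fi, base_cols])
      vals[c, fi, ] <- if (b > 0) 100 * (P[c, fi, ] - b) / b else NA_real_
    }
  }
  dimnames(vals) <- list(channels, NULL, NULL)
  structure(list(values = vals, freq_axis = freqs[fsel], time_axis = centers,
                 baseline_interval = baseline, channel_names = channels,
                 n_trials = nrow(ann)),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d ch x %d freqs (%g-%g Hz) x %d times (%g to %g s), %d trials\n",
              length(x$channel_names), length(x$freq_axis), min(x$freq_axis),
              max(x$freq_axis), length(x$time_axis), min(x$time_axis),
              max(x$time_axis), x$n_trials))
  invisible(x)
}

#' Mean of a time-frequency map over a band and interval
#'
#' @param map A `tf_map`.
#' @param channel Channel label.
#' @param band Hz interval.
#' @param interval Time interval, s relative to cue.
#' @return Mean percent change (scalar).
#' @export
tf_band_mean <- function(map, channel, band = c(8, 12), interval = c(1, 6)) {
  ci <- match(channel, map$channel_names)
  assert_that(!is.na(ci), "channel not in map")
  fs <- map$freq_axis >= band[1] & map$freq_axis <= band[2]
  ts <- map$time_axis >= interval[1] & map$time_axis <= interval[2]
  mean(map$values[ci, fs, ts])
}
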