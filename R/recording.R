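#' Annotated multichannel EEG recording
#'
#' The raw-material container of every signal stage: a channels-by-samples
#' matrix in microvolts, the sampling rate, ordered channel labels, and task
#' annotations (cue onset in seconds from recording start, duration, label).
#'
#' @param data Numeric matrix, channels x samples.
#' @param sfreq Sampling rate in Hz (> 0).
#' @param channel_names Character vector, one label per data row.
#' @param annotations Data frame with columns `onset`, `duration`, `label`
#'   (seconds, seconds, character); extra columns (e.g. `run`) are kept.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, channel_names,
                          annotations = empty_annotations()) {
  data <- as.matrix(data)
  assert_that(is.numeric(sfreq) && length(sfreq) == 1 && sfreq > 0,
              "sfreq must be a positive scalar")
  assert_that(nrow(data) == length(channel_names),
              "data must have one row per channel name")
  annotations <- as.data.frame(annotations)
  assert_that(all(c("onset", "duration", "label") %in% names(annotations)),
              "annotations need onset, duration and label columns")
  dur <- ncol(data) / sfreq
  if (nrow(annotations) > 0) {
    assert_that(all(annotations$onset >= 0 & annotations$onset + annotations$duration <= dur + 1e-9),
                "annotations must lie within the recording")
  }
  structure(list(data = data, sfreq = sfreq,
                 channel_names = as.character(channel_names),
                 annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), %d annotations\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq,
              nrow(x$annotations)))
  invisible(x)
}

empty_annotations <- function() {
  data.frame(onset = numeric(0), duration = numeric(0), label = character(0))
}

#' Recording duration in seconds
#' @param rec An [eeg_recording()].
#' @return Scalar seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$sfreq

#' Welch band power
#'
#' Average power spectral density integrated over a frequency band, estimated
#' by Welch's method (Hann-windowed overlapping segments). Used throughout as
#' the independent band-power oracle for the simulated mu/beta rhythms.
#'
#' @param x Numeric vector (single-channel signal).
#' @param sfreq Sampling rate, Hz.
#' @param band Length-2 numeric, Hz.
#' @param seg_len Segment length in seconds (default 1).
#' @return Band power (same units as `var(x)` restricted to the band).
#' @export
band_power <- function(x, sfreq, band, seg_len = 1) {
  n <- round(seg_len * sfreq)
  assert_that(length(x) >= n, "signal shorter than one Welch segment")
  step <- n %/% 2
  starts <- seq(1, length(x) - n + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))  # Hann
  u <- sum(w^2)
  freqs <- (seq_len(n) - 1) * sfreq / n
  keep <- freqs >= band[1] & freqs <= band[2]
  pxx <- rep(0, n)
  for (s in starts) {
    seg <- x[s:(s + n - 1)]
    seg <- (seg - mean(seg)) * w
    pxx <- pxx + Mod(stats::fft(seg))^2 / u
  }
  pxx <- pxx / length(starts)
  sum(pxx[keep]) / n * 2  # one-sided
}
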