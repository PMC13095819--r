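# Shared fixtures, built lazily so only the test files that need the large
# session pay for it. Everything is generated in code from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The reference competence-test session: 9 series, 19 channels, 256 Hz,
# erd_depth 0.4, snr 4, seed 1 (the desk-scale study conditions).
ref_session <- function() {
  fixture("ref_session", function() {
    generate_mi_session(synth_eeg_config(erd_depth = 0.4, snr = 4, seed = 1))
  })
}

# Its band-passed, windowed, outlier-screened window set.
ref_windows <- function() {
  fixture("ref_windows", function() {
    filt <- bandpass_fir(ref_session()$recording)
    reject_outlier_windows(epoch_and_window(filt))$windows
  })
}

# A small (2-series) high-separability session and its fitted decoder.
small_decoder <- function() {
  fixture("small_decoder", function() {
    s <- generate_mi_session(synth_eeg_config(erd_depth = 0.6, snr = 6,
                                              n_series = 2, seed = 11))
    ws <- reject_outlier_windows(epoch_and_window(bandpass_fir(s$recording)))$windows
    list(session = s, windows = ws, model = fit_decoder(ws))
  })
}

# Mean Welch band power at one channel over the 1-6 s post-cue span of all
# trials with a given label: the independent band-power oracle.
trial_band_power <- function(session, label, channel, band = c(8, 12)) {
  rec <- session$recording
  sf <- rec$sfreq
  ch <- match(channel, rec$channel_names)
  a <- session$annotations[session$annotations$label == label, ]
  mean(vapply(seq_len(nrow(a)), function(i) {
    i0 <- round((a$onset[i] + 1) * sf) + 1
    band_power(rec$data[ch, i0:(i0 + 5 * sf - 1)], sf, band)
  }, numeric(1)))
}

# A constant-label decision stream at the closed-loop rate.
constant_stream <- function(label, duration, classes = c("relax", "left_hand",
                                                         "right_hand"),
                            step = 0.0625) {
  times <- seq(step, duration, by = step)
  d <- data.frame(time = times, label = label)
  for (cl in classes) d[[paste0("p_", cl)]] <- as.numeric(cl == label)
  structure(list(decisions = d, window_length = 2, step = step,
                 classes = classes),
            class = "decision_stream")
}

# A scripted decision stream: labels follow (label, duration) segments.
scripted_stream <- function(labels, durations, classes = c("relax",
                                                           "left_hand",
                                                           "right_hand"),
                            step = 0.0625) {
  total <- sum(durations)
  times <- seq(step, total, by = step)
  bounds <- cumsum(durations)
  lab <- labels[findInterval(times - 1e-12, c(0, bounds), rightmost.closed = TRUE)]
  d <- data.frame(time = times, label = lab)
  for (cl in classes) d[[paste0("p_", cl)]] <- as.numeric(lab == cl)
  structure(list(decisions = d, window_length = 2, step = step,
                 classes = classes),
            class = "decision_stream")
}
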