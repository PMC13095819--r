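make_tone_rec <- function(freq, sfreq = 256, dur = 10, nch = 3) {
  t_axis <- (seq_len(dur * sfreq) - 1) / sfreq
  x <- sin(2 * pi * freq * t_axis)
  eeg_recording(matrix(rep(x, each = nch), nrow = nch), sfreq,
                c("C3", "Cz", "C4"))
}

test_that("band-pass keeps the pass band and crushes stop bands", {
  in20 <- make_tone_rec(20)
  out20 <- bandpass_fir(in20)
  mid <- 500:2000  # away from edges
  expect_equal(stats::sd(out20$data[1, mid]), stats::sd(in20$data[1, mid]),
               tolerance = 0.1)
  in2 <- make_tone_rec(2)
  out2 <- bandpass_fir(in2)
  expect_lt(sqrt(mean(out2$data[1, mid]^2)) / sqrt(mean(in2$data[1, mid]^2)),
            0.01)
})

test_that("filtered white noise concentrates its power in 8-30 Hz", {
  withr::with_seed(5, {
    x <- matrix(rnorm(3 * 256 * 30), nrow = 3)
  })
  rec <- eeg_recording(x, 256, c("C3", "Cz", "C4"))
  out <- bandpass_fir(rec)
  inband <- band_power(out$data[1, ], 256, c(8, 30))
  outband <- band_power(out$data[1, ], 256, c(0.5, 6)) +
    band_power(out$data[1, ], 256, c(35, 127))
  expect_gt(inband / outband, 20)
})

test_that("filtering is idempotent in the pass band", {
  rec <- make_tone_rec(15)
  once <- bandpass_fir(rec)
  twice <- bandpass_fir(once)
  mid <- 500:2000
  rel <- sqrt(mean((twice$data[1, mid] - once$data[1, mid])^2)) /
    sqrt(mean(once$data[1, mid]^2))
  expect_lt(rel, 0.01)
})

test_that("band edges outside Nyquist are rejected", {
  rec <- make_tone_rec(10)
  expect_error(bandpass_fir(rec, 8, 200), "Nyquist")
  expect_error(bandpass_fir(rec, 0, 30), "Nyquist")
})

test_that("epoching yields 4 windows per trial at the protocol settings", {
  s <- ref_session()
  ws <- epoch_and_window(s$recording)
  expect_equal(n_windows(ws), 162 * 4)
  expect_equal(dim(ws$windows)[3], 2 * 256)
  # window starts at cue+1..cue+4 -> provenance is a partition by trial
  expect_equal(as.vector(table(ws$trial_id)), rep(4L, 162))
  # labels inherited from cues, runs from series
  first <- which(ws$trial_id == 1)
  expect_equal(unique(ws$labels[first]), s$annotations$label[1])
  expect_equal(unique(ws$run_id[first]), 1L)
})

test_that("span equal to the window gives exactly one window per trial", {
  s <- generate_mi_session(synth_eeg_config(n_series = 1, seed = 3))
  ws <- epoch_and_window(s$recording, epoch_span = c(1, 3))
  expect_equal(n_windows(ws), nrow(s$annotations))
})

test_that("truncated trials are skipped with a warning, not an error", {
  s <- generate_mi_session(synth_eeg_config(n_series = 1, seed = 3))
  rec <- s$recording
  cut <- round((rec$annotations$onset[nrow(rec$annotations)] + 3) * rec$sfreq)
  rec2 <- eeg_recording(rec$data[, 1:cut], rec$sfreq, rec$channel_names)
  expect_warning(ws <- epoch_and_window(rec2, rec$annotations),
                 "truncated")
  expect_equal(n_windows(ws), (nrow(rec$annotations) - 1) * 4)
})

clean_windows_50 <- function() {
  fixture("clean_ws_50", function() {
    withr::with_seed(55, {
      arr <- array(rnorm(51 * 3 * 128), c(51, 3, 128))
      labeled_windows(arr, rep("relax", 51), 1:51, rep(1:3, 17), 2, 1, 64,
                      c("C3", "Cz", "C4"))
    })
  })
}

test_that("outlier rejection removes exactly an injected artifact window", {
  ws <- clean_windows_50()
  bad <- 17L
  ws$windows[bad, , ] <- ws$windows[bad, , ] * 100
  out <- reject_outlier_windows(ws)
  expect_equal(out$rejected, bad)
  # oracle: recompute the robust z of the log-variance directly
  lv <- log(apply(ws$windows[, 1, ], 1, var))
  z <- abs(lv - median(lv)) / mad(lv)
  expect_gt(z[bad], 3.5)
  expect_true(all(z[-bad] < 3.5))
  # removal only: surviving windows are untouched and in order
  expect_identical(out$windows$windows[bad, , ],
                   ws$windows[bad + 1L, , ])
})

test_that("rejection is a no-op at z_max = Inf and on identical windows", {
  ws <- clean_windows_50()
  out <- reject_outlier_windows(ws, z_max = Inf)
  expect_identical(out$windows$windows, ws$windows)
  expect_length(out$rejected, 0)
  # identical windows: zero MAD and zero SD guard, nothing rejected
  flat <- ws
  for (i in seq_len(n_windows(ws))) flat$windows[i, , ] <- ws$windows[1, , ]
  out2 <- reject_outlier_windows(flat)
  expect_length(out2$rejected, 0)
})

test_that("rejection refuses to empty a class", {
  s <- generate_mi_session(synth_eeg_config(n_series = 1, seed = 13))
  ws <- epoch_and_window(bandpass_fir(s$recording))
  keep <- c(which(ws$labels == "relax")[1:2], which(ws$labels != "relax"))
  ws2 <- mibci:::ws_subset(ws, sort(keep))
  ws2$windows[which(ws2$labels == "relax")[1], , ] <-
    ws2$windows[which(ws2$labels == "relax")[1], , ] * 50
  expect_error(reject_outlier_windows(ws2, z_max = 0.5), "relax")
})
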