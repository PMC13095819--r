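#' Configuration for the synthetic motor-imagery EEG generator
#'
#' Defines the study conditions the generator emulates: a three-class
#' kinesthetic motor-imagery session (relax / left hand / right hand) in
#' which imagery suppresses the contralateral sensorimotor mu and beta
#' rhythms (event-related desynchronization, ERD).
#'
#' @param sampling_rate Hz. The acquisition rate is not fixed by the protocol
#'   this emulates; 256 Hz is a common clinical-amplifier default.
#' @param n_series Number of runs/series per session (default 9, the
#'   competence-test schedule).
#' @param trials_per_task Trials of each task per series (default 6).
#' @param task_set Character subset of `c("relax", "left_hand", "right_hand")`.
#' @param trial_duration Trial length in seconds; must be >= 6 so the 1-6 s
#'   post-cue epoch fits (default 8, leaving a clean pre-cue baseline).
#' @param erd_depth Fraction in `[0, 1]`: band-power attenuation of the
#'   contralateral rhythm during imagery (0.4 means task power = 60% of rest).
#' @param erd_band Hz interval of the rhythm whose suppression is the ground
#'   truth (default mu, 8-12 Hz).
#' @param snr Ratio of mu-rhythm power to total broadband noise power at the
#'   rhythm's home channel.
#' @param amp_jitter_sd Log-scale SD of optional per-trial rhythm amplitude
#'   jitter (power-preserving lognormal). The default generator uses constant
#'   source amplitude with random phase — window-to-window variability then
#'   comes from the broadband noise alone; set this above 0 to stress the
#'   decoder with trial-level power fluctuations.
#' @param seed Integer seed; identical seeds give bit-identical sessions.
#' @return A validated list of class `synth_eeg_config`.
#' @export
synth_eeg_config <- function(sampling_rate = 256, n_series = 9,
                             trials_per_task = 6,
                             task_set = c("relax", "left_hand", "right_hand"),
                             trial_duration = 8, erd_depth = 0.4,
                             erd_band = c(8, 12), snr = 4,
                             amp_jitter_sd = 0, seed = 1) {
  known <- c("relax", "left_hand", "right_hand")
  bad <- setdiff(task_set, known)
  assert_that(length(bad) == 0,
              paste0("unknown task label(s): ", paste(bad, collapse = ", ")))
  assert_that(erd_depth >= 0 && erd_depth <= 1, "erd_depth must lie in [0, 1]")
  assert_that(trial_duration >= 6,
              "configuration error: trial_duration must be >= 6 s (1-6 s epoch must fit)")
  assert_that(sampling_rate >= 2 * erd_band[2],
              "sampling_rate must be at least twice the upper erd_band edge")
  assert_that(n_series >= 1 && trials_per_task >= 1, "counts must be positive")
  structure(list(sampling_rate = sampling_rate, n_series = n_series,
                 trials_per_task = trials_per_task, task_set = task_set,
                 trial_duration = trial_duration, erd_depth = erd_depth,
                 erd_band = erd_band, snr = snr,
                 amp_jitter_sd = amp_jitter_sd, seed = seed),
            class = "synth_eeg_config")
}

# 1/f amplitude noise per channel, unit variance. The 1/f scaling is floored
# below 0.5 Hz so infra-slow drift does not swamp the record.
pink_noise <- function(n, sfreq) {
  n2 <- stats::nextn(n, 2)  # pad for a fast transform, truncate afterwards
  w <- stats::rnorm(n2)
  W <- stats::fft(w)
  k <- seq_len(n2) - 1
  f <- pmin(k, n2 - k) * sfreq / n2
  s <- 1 / sqrt(pmax(f, 0.5))
  s[1] <- 0
  x <- Re(stats::fft(W * s, inverse = TRUE))[seq_len(n)] / n2
  x / stats::sd(x)
}

# Rhythm source: a train of sinusoidal bursts with independent random phase.
# Consecutive bursts are sqrt-Hann windowed with 50% overlap (sum of squared
# windows = 1), so expected power equals that of a unit-amplitude sinusoid
# (0.5) while the phase decorrelates on the burst timescale — narrowband
# activity like sensorimotor mu, not a session-long coherent oscillation.
source_oscillation <- function(n, sfreq, freq, burst_len = 1) {
  hop <- max(2, round(burst_len * sfreq / 2))
  L <- 2 * hop
  j <- seq_len(L) - 1
  win <- sqrt(0.5 - 0.5 * cos(2 * pi * j / L))
  t_axis <- (seq_len(n + L) - 1) / sfreq
  s <- numeric(n + L)
  starts <- seq(1 - hop, n, by = hop)
  for (st in starts) {
    phi <- stats::runif(1, 0, 2 * pi)
    i0 <- max(1, st)
    i1 <- min(n + L, st + L - 1)
    wseg <- win[(i0 - st + 1):(i1 - st + 1)]
    s[i0:i1] <- s[i0:i1] + wseg * sin(2 * pi * freq * t_axis[i0:i1] + phi)
  }
  s[seq_len(n)]
}

# Cosine-smooth a piecewise-constant envelope with a short moving average.
smooth_envelope <- function(e, sfreq, ramp = 0.2) {
  k <- max(3, round(ramp * sfreq))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(k) / (k + 1))
  w <- w / sum(w)
  as.numeric(stats::filter(c(rep(e[1], k), e, rep(e[length(e)], k)), w,
                           sides = 2))[(k + 1):(k + length(e))]
}

#' Generate a synthetic motor-imagery EEG session
#'
#' Produces an annotated multichannel recording emulating an open-loop
#' calibration / competence-test session: `n_series` runs, each containing
#' `trials_per_task` randomly ordered cues of every task. Background activity
#' is independent 1/f (pink) noise per channel; two rhythm sources (10 Hz mu
#' plus a half-power 20 Hz beta, each a train of 1-s sinusoidal bursts with
#' independent random phases) sit at the C3 and C4 positions and project
#' to the scalp through a Gaussian kernel over great-circle electrode
#' distance (width 0.35 rad), giving focal smooth topographies. During
#' left-hand imagery the C4-side source power is attenuated by
#' `1 - erd_depth` (right-hand: C3 side; relax: none), from 0.5 s to 6.5 s
#' after the cue with 0.2 s ramps, so both the 1-6 s decoding epoch and a
#' clean -1-0 s baseline are realized.
#'
#' @param config A [synth_eeg_config()].
#' @param montage A [montage()] containing C3 and C4 (default
#'   `standard_montage("standard19")`).
#' @return A list with `recording` (an [eeg_recording()] whose annotations
#'   carry `onset`, `duration`, `label`, `run`) and `annotations` (the same
#'   data frame).
#' @examples
#' s <- generate_mi_session(synth_eeg_config(n_series = 1, seed = 42))
#' table(s$annotations$label)
#' @export
generate_mi_session <- function(config, montage = standard_montage("standard19")) {
  stopifnot(inherits(config, "synth_eeg_config"), inherits(montage, "montage"))
  sf <- config$sampling_rate
  tasks <- config$task_set
  n_trials <- config$n_series * config$trials_per_task * length(tasks)
  lead_in <- 2                       # pre-session padding: first-trial baseline
  dur <- lead_in + n_trials * config$trial_duration + 1
  n <- round(dur * sf)

  with_seed(config$seed, {
    ## cue schedule: balanced and shuffled within each series
    labels <- unlist(lapply(seq_len(config$n_series), function(s) {
      sample(rep(tasks, config$trials_per_task))
    }))
    onsets <- lead_in + (seq_len(n_trials) - 1) * config$trial_duration
    runs <- rep(seq_len(config$n_series),
                each = config$trials_per_task * length(tasks))

    pos <- montage$positions
    src_pos <- list(C3 = pos["C3", ], C4 = pos["C4", ])
    # imagery suppresses the CONTRALATERAL rhythm
    suppressed_by <- c(left_hand = "C4", right_hand = "C3")

    mu_power <- config$snr            # noise power per channel is 1
    amp <- c(mu = sqrt(2 * mu_power), beta = sqrt(2 * mu_power / 2))
    freqs <- c(mu = 10, beta = 20)
    atten <- sqrt(1 - config$erd_depth)

    data <- matrix(0, nrow = length(montage$channel_names), ncol = n)
    for (ch in seq_len(nrow(data))) data[ch, ] <- pink_noise(n, sf)

    for (side in c("C3", "C4")) {
      env <- rep(1, n)
      for (i in seq_len(n_trials)) {
        jit <- if (config$amp_jitter_sd > 0) {
          exp(config$amp_jitter_sd * stats::rnorm(1) - config$amp_jitter_sd^2)
        } else 1
        i0 <- round(onsets[i] * sf) + 1
        i1 <- min(n, round((onsets[i] + config$trial_duration) * sf))
        env[i0:i1] <- jit
        if (identical(unname(suppressed_by[labels[i]]), side)) {
          a0 <- round((onsets[i] + 0.5) * sf) + 1
          a1 <- min(n, round((onsets[i] + 6.5) * sf))
          env[a0:a1] <- jit * atten
        }
      }
      env <- smooth_envelope(env, sf)
      source_sig <- env * (amp["mu"] * source_oscillation(n, sf, freqs["mu"]) +
                           amp["beta"] * source_oscillation(n, sf, freqs["beta"]))
      gains <- exp(-great_circle_dist(pos, src_pos[[side]])^2 / (2 * 0.35^2))
      data <- data + tcrossprod(gains, source_sig)
    }

    ann <- data.frame(onset = onsets, duration = config$trial_duration,
                      label = labels, run = runs)
    rec <- eeg_recording(data, sf, montage$channel_names, ann)
    list(recording = rec, annotations = ann)
  })
}
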