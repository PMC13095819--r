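#' Competence-test cue schedule
#'
#' Builds the cue sequence of a screening/calibration session: `n_series`
#' series, each containing exactly `trials_per_task` cues of every task in
#' seeded-random order (162 cues at the defaults: 9 series x 6 trials x 3
#' tasks, i.e. 54 per task). The two 1-minute rest baselines that precede the
#' series (eyes open, then eyes closed) are carried as metadata.
#'
#' @param n_series Number of series (default 9).
#' @param trials_per_task Cues of each task per series (default 6).
#' @param tasks Task labels (default the three motor-imagery states).
#' @param seed Integer seed for the within-series shuffles.
#' @return Object of class `cue_schedule`: data frame `cues` (`series`,
#'   `trial`, `label`) and `baselines` (metadata data frame).
#' @export
schedule_competence_test <- function(n_series = 9, trials_per_task = 6,
                                     tasks = c("relax", "left_hand", "right_hand"),
                                     seed = 1) {
  assert_that(n_series >= 1 && trials_per_task >= 1 && length(tasks) >= 1,
              "counts must be positive")
  cues <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_series), function(s) {
      data.frame(series = s,
                 trial = seq_len(trials_per_task * length(tasks)),
                 label = sample(rep(tasks, trials_per_task)))
    }))
  })
  structure(list(cues = cues,
                 baselines = data.frame(
                   phase = c("rest_eyes_open", "rest_eyes_closed"),
                   duration = c(60, 60))),
            class = "cue_schedule")
}

#' Training exercise definition
#'
#' An ordered sequence of mental states with required hold durations, to be
#' completed within an allotted time (e.g. right-hand imagery 6 s, relax 3 s,
#' left-hand imagery 3 s).
#'
#' @param states Character vector of state labels.
#' @param holds Required hold per state, seconds (> 0).
#' @param allotted_time Total time allowed, s; must be >= `sum(holds)`.
#' @return Object of class `exercise`.
#' @export
exercise <- function(states, holds, allotted_time) {
  assert_that(length(states) == length(holds) && length(states) >= 1,
              "states and holds must have equal positive length")
  assert_that(all(holds > 0), "holds must be positive")
  assert_that(allotted_time >= sum(holds),
              "allotted_time must be at least the sum of holds")
  structure(list(states = as.character(states), holds = as.numeric(holds),
                 allotted_time = allotted_time),
            class = "exercise")
}

#' Composite difficulty score of an exercise
#'
#' `score = n_states * (sum(holds) / allotted_time)`: the number of mental
#' states required multiplied by the required-to-allotted time ratio. It is
#' dimensionless, grows with the number of alternations and with temporal
#' tightness, and is invariant to relabeling states or permuting equal-hold
#' segments. The arithmetic combining the two published ingredients is this
#' package's own convention.
#'
#' @param ex An [exercise()].
#' @return Positive scalar.
#' @export
difficulty_score <- function(ex) {
  stopifnot(inherits(ex, "exercise"))
  assert_that(ex$allotted_time > 0, "allotted_time must be positive")
  length(ex$states) * sum(ex$holds) / ex$allotted_time
}

#' Evaluate an exercise against a decision stream
#'
#' Dwell-based validation: segments must be completed in order; every
#' decision whose label equals the current segment's state contributes one
#' decision period of dwell (nothing resets on label flicker). A segment
#' completes when its cumulative dwell reaches the required hold; the
#' exercise succeeds if the final segment completes within the allotted time
#' from the exercise start. A consecutive-hold variant (dwell resets on any
#' non-matching decision) is available via `rule`.
#'
#' @param stream A `decision_stream` (from [stream_decode()]), assumed to
#'   start at the exercise start.
#' @param ex An [exercise()].
#' @param rule `"cumulative"` (default) or `"consecutive"`.
#' @return Object of class `exercise_result`: `success`, `completion_time`
#'   (s from exercise start, `NA` unless success), `attempts` (1),
#'   `achieved_holds` per segment.
#' @export
evaluate_exercise <- function(stream, ex, rule = c("cumulative", "consecutive")) {
  stopifnot(inherits(stream, "decision_stream"), inherits(ex, "exercise"))
  rule <- match.arg(rule)
  d <- stream$decisions
  d <- d[d$time <= ex$allotted_time + 1e-9, , drop = FALSE]
  achieved <- numeric(length(ex$states))
  seg <- 1L
  success <- FALSE
  completion <- NA_real_
  if (nrow(d) > 0) {
    for (i in seq_len(nrow(d))) {
      if (d$label[i] == ex$states[seg]) {
        achieved[seg] <- achieved[seg] + stream$step
      } else if (rule == "consecutive") {
        achieved[seg] <- 0
      }
      if (achieved[seg] >= ex$holds[seg] - 1e-9) {
        if (seg == length(ex$states)) {
          success <- TRUE
          completion <- d$time[i]
          break
        }
        seg <- seg + 1L
      }
    }
  }
  structure(list(success = success, completion_time = completion,
                 attempts = 1L, achieved_holds = achieved),
            class = "exercise_result")
}

#' Session success rate
#'
#' Number of successfully completed exercises divided by the number of
#' attempts within the session.
#'
#' @param results List of `exercise_result` objects (or a `session_record`).
#' @return Fraction in `[0, 1]`; zero attempts is an error.
#' @export
session_success_rate <- function(results) {
  if (inherits(results, "session_record")) results <- results$results
  assert_that(length(results) >= 1, "success rate undefined with zero attempts")
  mean(vapply(results, function(r) isTRUE(r$success), logical(1)))
}

#' Default difficulty ramp of the demo training course
#'
#' Exercise template for session `t` of a simulated 10-session course: one
#' state initially, one more every 3 sessions; the allotted-time slack
#' tightens by 25% every 2 sessions. Used only by
#' [simulate_training_course()].
#'
#' @param session_index 1-based session number (t1-t10).
#' @param tasks State pool.
#' @return An [exercise()].
#' @export
ramp_exercise <- function(session_index,
                          tasks = c("right_hand", "relax", "left_hand")) {
  n_states <- min(1 + (session_index - 1) %/% 3, length(tasks) + 1)
  states <- rep(tasks, length.out = n_states)
  holds <- rep(3, n_states)
  slack0 <- 2                                  # initial allotted = 2x required
  tighten <- 0.75^((session_index - 1) %/% 2)  # +25% tightness every 2 sessions
  # floor: every segment costs ~1.5 s of closed-loop latency (filter delay +
  # 2-s window turnover), so below sum(holds) + 2 s per segment an exercise
  # is uncompletable by construction rather than difficult
  allotted <- max(sum(holds) * slack0 * tighten, sum(holds) + 2 * n_states)
  exercise(states, holds, allotted)
}

#' Simulate a closed-loop training course
#'
#' End-to-end demo of the training protocol: per session, a decoder is
#' calibrated on a synthetic open-loop session, then each exercise of the
#' session's difficulty ramp is attempted by streaming a fresh synthetic
#' recording that follows the exercise script (the subject "performs" each
#' required state for its scheduled span) through [stream_decode()] and
#' [evaluate_exercise()].
#'
#' @param n_sessions Number of sessions (default 10, t1-t10).
#' @param exercises_per_session Attempts per session (default 4).
#' @param config A [synth_eeg_config()] describing the subject's signal
#'   quality; its `n_series` is used for the calibration sessions.
#' @param montage A [montage()].
#' @param seed Integer master seed.
#' @return Object of class `training_course`: data frame `sessions`
#'   (`session`, `difficulty`, `success_rate`) and the per-exercise log.
#' @export
simulate_training_course <- function(n_sessions = 10, exercises_per_session = 4,
                                     config = synth_eeg_config(erd_depth = 0.5,
                                                               n_series = 3),
                                     montage = standard_montage("standard19"),
                                     seed = 1) {
  log <- list()
  sess <- data.frame(session = seq_len(n_sessions), difficulty = NA_real_,
                     success_rate = NA_real_)
  for (t in seq_len(n_sessions)) {
    cal_cfg <- config
    cal_cfg$seed <- seed + 1000L * t
    cal <- generate_mi_session(cal_cfg, montage)
    filt <- bandpass_fir(cal$recording)
    ws <- epoch_and_window(filt)
    model <- fit_decoder(reject_outlier_windows(ws)$windows)
    ex <- ramp_exercise(t)
    results <- vector("list", exercises_per_session)
    for (a in seq_len(exercises_per_session)) {
      scr <- script_recording(ex, config, montage, seed = seed + 1000L * t + a)
      stream <- stream_decode(scr, model)
      # the exercise clock starts once the decoder is warm (2-s pre-roll)
      stream$decisions <- stream$decisions[stream$decisions$time > 2 + 1e-9, ,
                                           drop = FALSE]
      stream$decisions$time <- stream$decisions$time - 2
      results[[a]] <- evaluate_exercise(stream, ex)
    }
    sess$difficulty[t] <- difficulty_score(ex)
    sess$success_rate[t] <- session_success_rate(results)
    log[[t]] <- results
  }
  structure(list(sessions = sess, log = log), class = "training_course")
}

# A recording in which the subject performs the exercise script: each state
# is held for its scheduled share of the allotted time (proportional to its
# required hold), realized with the same source model as the cue generator.
script_recording <- function(ex, config, montage, seed, preroll = 2) {
  share <- ex$holds / sum(ex$holds) * ex$allotted_time
  # 2-s pre-roll of the first state so the decoder's window is full when the
  # exercise clock starts
  spans <- data.frame(onset = preroll + cumsum(c(0, utils::head(share, -1))),
                      duration = share, label = ex$states)
  spans <- rbind(data.frame(onset = 0, duration = preroll,
                            label = ex$states[1]), spans)
  cfg <- config
  cfg$seed <- seed
  gen_scripted_recording(spans, cfg, montage, preroll + ex$allotted_time + 0.5)
}

# Shared scripted-state generator: like generate_mi_session but with an
# explicit state timeline instead of a cue schedule.
gen_scripted_recording <- function(spans, config, montage, total_duration) {
  sf <- config$sampling_rate
  n <- round(total_duration * sf)
  suppressed_by <- c(left_hand = "C4", right_hand = "C3")
  mu_power <- config$snr
  amp <- c(mu = sqrt(2 * mu_power), beta = sqrt(2 * mu_power / 2))
  atten <- sqrt(1 - config$erd_depth)
  pos <- montage$positions
  with_seed(config$seed, {
    data <- matrix(0, nrow = length(montage$channel_names), ncol = n)
    for (ch in seq_len(nrow(data))) data[ch, ] <- pink_noise(n, sf)
    for (side in c("C3", "C4")) {
      env <- rep(1, n)
      for (i in seq_len(nrow(spans))) {
        if (identical(unname(suppressed_by[spans$label[i]]), side)) {
          a0 <- round(spans$onset[i] * sf) + 1
          a1 <- min(n, round((spans$onset[i] + spans$duration[i]) * sf))
          env[a0:a1] <- atten
        }
      }
      env <- smooth_envelope(env, sf)
      sig <- env * (amp["mu"] * source_oscillation(n, sf, 10) +
                    amp["beta"] * source_oscillation(n, sf, 20))
      gains <- exp(-great_circle_dist(pos, pos[side, ])^2 / (2 * 0.35^2))
      data <- data + tcrossprod(gains, sig)
    }
    eeg_recording(data, sf, montage$channel_names,
                  data.frame(onset = spans$onset, duration = spans$duration,
                             label = spans$label))
  })
}
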