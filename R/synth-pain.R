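#' Configuration for the pain-diary simulator
#'
#' Defines the data-generating structure the outcome analytics assume: each
#' subject keeps a daily diary of continuous pain (min/avg/max on the 0-10
#' numeric rating scale, NRS) and paroxysmal episodes (intensity x duration),
#' across study periods (one pre-intervention month `m-1`, then training and
#' post-training weeks `w1`-`w4`). Daily paroxysmal pain volume is lognormal
#' around a subject- and period-specific median:
#' `median = baseline_volume_median * period_multiplier * exp(b_i)`,
#' with `b_i ~ N(0, subject_sd^2)` the subject's random intercept (baseline
#' heterogeneity in pain perception) and lognormal day-to-day dispersion.
#' Episode counts are Poisson; volumes are positive and right-skewed, like
#' observed paroxysmal pain burdens.
#'
#' The default period multipliers (w1 0.65, w2 0.45, w3 0.36, w4 0.14)
#' encode the progressive ~35/55/64/86% median reductions the intervention
#' is expected to produce; the default baseline median volume (335 NRS·h)
#' and NRS (5) match a moderate-burden cohort.
#'
#' @param n_subjects Number of subjects (default 6).
#' @param days_per_period Named integer vector, days per period.
#' @param baseline_volume_median NRS·hours (default 335).
#' @param baseline_nrs Average continuous pain at baseline (default 5).
#' @param subject_sd SD of the log-scale subject random intercept.
#' @param period_multipliers Named positive factors on the volume median.
#' @param episode_rate Mean paroxysmal episodes per day (Poisson).
#' @param noise_model List: `type = "lognormal"`, `sdlog` day-to-day
#'   dispersion of volume (default 0.8, a typical within-subject spread for
#'   right-skewed daily pain burdens).
#' @param seed Integer seed.
#' @return A validated list of class `pain_sim_config`.
#' @export
pain_sim_config <- function(n_subjects = 6,
                            days_per_period = c("m-1" = 30, w1 = 7, w2 = 7,
                                                w3 = 7, w4 = 7),
                            baseline_volume_median = 335,
                            baseline_nrs = 5,
                            subject_sd = 0.3,
                            period_multipliers = c("m-1" = 1, w1 = 0.65,
                                                   w2 = 0.45, w3 = 0.36,
                                                   w4 = 0.14),
                            episode_rate = 12,
                            noise_model = list(type = "lognormal", sdlog = 0.8),
                            seed = 1) {
  assert_that(all(period_multipliers > 0), "period multipliers must be positive")
  assert_that(all(days_per_period >= 1), "need at least 1 day per period")
  assert_that(episode_rate >= 0, "episode_rate must be non-negative")
  assert_that(setequal(names(days_per_period), names(period_multipliers)),
              "days_per_period and period_multipliers must name the same periods")
  assert_that(identical(noise_model$type, "lognormal"),
              "noise_model$type must be 'lognormal'")
  structure(list(n_subjects = n_subjects, days_per_period = days_per_period,
                 baseline_volume_median = baseline_volume_median,
                 baseline_nrs = baseline_nrs, subject_sd = subject_sd,
                 period_multipliers = period_multipliers,
                 episode_rate = episode_rate, noise_model = noise_model,
                 seed = seed),
            class = "pain_sim_config")
}

#' Generate synthetic pain diaries
#'
#' Long-format diary: one daily row per subject and day (NRS triplet, no
#' episode fields) plus one row per paroxysmal episode (intensity, duration;
#' no NRS fields). Daily NRS triplets always satisfy `min <= avg <= max`
#' within 0-10. Daily volume is realized by drawing the day's target volume
#' (lognormal around the subject/period median), a Poisson episode count,
#' and splitting the volume across episodes with Dirichlet(1) weights and
#' integer intensities; a zero episode count yields a zero-volume day.
#' Reproducible bit-for-bit from `config$seed`.
#'
#' @param config A [pain_sim_config()].
#' @return A data frame of class `pain_diary` with columns `subject_id`,
#'   `day` (1-based within period), `period`, `row_type`
#'   (`"daily"`/`"episode"`), `nrs_min`, `nrs_avg`, `nrs_max`,
#'   `episode_intensity`, `episode_duration_h`. Attribute `truth` stores the
#'   per-subject intercepts and config for test oracles.
#' @export
generate_pain_diaries <- function(config) {
  stopifnot(inherits(config, "pain_sim_config"))
  periods <- names(config$days_per_period)
  sdlog <- config$noise_model$sdlog
  with_seed(config$seed, {
    b <- stats::rnorm(config$n_subjects, 0, config$subject_sd)
    nrs_b <- stats::rnorm(config$n_subjects, 0, 0.75)
    rows <- vector("list", 0)
    for (i in seq_len(config$n_subjects)) {
      sid <- sprintf("S%02d", i)
      for (p in periods) {
        mult <- config$period_multipliers[[p]]
        for (d in seq_len(config$days_per_period[[p]])) {
          med <- config$baseline_volume_median * mult * exp(b[i])
          v <- med * exp(if (sdlog > 0) stats::rnorm(1, 0, sdlog) else 0)
          n_ep <- stats::rpois(1, config$episode_rate)
          # NRS triplet; continuous pain responds less than paroxysmal burden
          avg <- config$baseline_nrs * mult^0.25 + nrs_b[i] +
            stats::rnorm(1, 0, 0.6)
          avg <- round(2 * min(10, max(0, avg))) / 2
          lo <- round(2 * min(avg, max(0, avg - abs(stats::rnorm(1, 1.5, 0.7))))) / 2
          hi <- round(2 * max(avg, min(10, avg + abs(stats::rnorm(1, 1.5, 0.7))))) / 2
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = sid, day = d, period = p, row_type = "daily",
            nrs_min = lo, nrs_avg = avg, nrs_max = hi,
            episode_intensity = NA_real_, episode_duration_h = NA_real_)
          if (n_ep > 0 && v > 0) {
            w <- stats::rgamma(n_ep, 1, 1)
            if (sum(w) == 0) w <- rep(1, n_ep)
            w <- w / sum(w)
            intensity <- sample(2:9, n_ep, replace = TRUE)
            rows[[length(rows) + 1]] <- data.frame(
              subject_id = sid, day = d, period = p, row_type = "episode",
              nrs_min = NA_real_, nrs_avg = NA_real_, nrs_max = NA_real_,
              episode_intensity = intensity,
              episode_duration_h = w * v / intensity)
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(subject_intercepts = b, config = config)
    class(out) <- c("pain_diary", class(out))
    out
  })
}
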