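#' Daily paroxysmal pain volume
#'
#' The per-day paroxysmal burden statistic: the sum over episodes of
#' intensity x self-reported duration — an area-under-the-curve surrogate
#' with units NRS·hours. A day without episodes has volume 0.
#'
#' @param intensity Episode intensities (NRS 0-10).
#' @param duration_h Episode durations in hours (> 0), same length.
#' @return Scalar volume, NRS·hours.
#' @examples
#' pain_volume(c(3, 7), c(0.5, 1))  # 8.5
#' @export
pain_volume <- function(intensity, duration_h) {
  assert_that(length(intensity) == length(duration_h),
              "intensity and duration_h must have equal length")
  if (length(intensity) == 0) return(0)
  assert_that(all(intensity >= 0 & intensity <= 10),
              "episode intensity must lie in [0, 10]")
  assert_that(all(duration_h > 0), "episode durations must be positive")
  sum(intensity * duration_h)
}

# One row per subject/period/day with the requested daily measure.
daily_values <- function(diary, measure = c("volume", "nrs_min", "nrs_avg",
                                            "nrs_max")) {
  measure <- match.arg(measure)
  daily <- diary[diary$row_type == "daily", , drop = FALSE]
  if (measure == "volume") {
    ep <- diary[diary$row_type == "episode", , drop = FALSE]
    key <- function(d) paste(d$subject_id, d$period, d$day, sep = "\r")
    vol <- tapply(ep$episode_intensity * ep$episode_duration_h, key(ep), sum)
    v <- as.numeric(vol[key(daily)])
    v[is.na(v)] <- 0
    data.frame(subject_id = daily$subject_id, period = daily$period,
               day = daily$day, value = v)
  } else {
    data.frame(subject_id = daily$subject_id, period = daily$period,
               day = daily$day, value = daily[[measure]])
  }
}

#' Percent variation of a period median from baseline
#'
#' `100 * (median - baseline_median) / baseline_median`, rounded half away
#' from zero to `digits` decimals for table display; `NA` when the baseline
#' median is zero (variation undefined).
#'
#' @param med Period median(s).
#' @param baseline_med Baseline (m-1) median.
#' @param digits Decimals for display rounding (default 2); `Inf` disables.
#' @return Percent variation (numeric, possibly `NA`).
#' @export
variation_pct <- function(med, baseline_med, digits = 2) {
  out <- ifelse(baseline_med == 0, NA_real_,
                100 * (med - baseline_med) / baseline_med)
  if (is.finite(digits)) out <- round_half_up(out, digits)
  out
}

#' Period summary table of a diary measure
#'
#' Quantiles (0.25 / median / 0.75) of the daily values within each period,
#' per patient and/or pooled over the cohort (`"All"` rows concatenate every
#' patient's daily values), with the percent variation of each period median
#' from the patient's (or pooled) baseline `m-1` median.
#'
#' @param diary A [generate_pain_diaries()]-shaped long diary.
#' @param measure `"volume"`, `"nrs_min"`, `"nrs_avg"` or `"nrs_max"`.
#' @param grouping `"both"` (default), `"per_patient"` or `"pooled"`.
#' @param baseline Baseline period label (default `"m-1"`).
#' @return Data frame: `patient`, `period`, `q25`, `median`, `q75`,
#'   `variation_pct` (vs the baseline median, `NA` for the baseline row or a
#'   zero baseline). Periods keep diary order; an empty period yields an
#'   all-`NA` row.
#' @export
summarize_periods <- function(diary, measure = "volume",
                              grouping = c("both", "per_patient", "pooled"),
                              baseline = "m-1") {
  grouping <- match.arg(grouping)
  dv <- daily_values(diary, measure)
  assert_that(baseline %in% dv$period, "baseline period absent from the diary")
  periods <- unique(dv$period)
  one_block <- function(vals_by_period, patient) {
    qs <- lapply(vals_by_period, function(v) {
      if (length(v) == 0) rep(NA_real_, 3) else
        stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    })
    med_base <- qs[[baseline]][2]
    do.call(rbind, lapply(names(qs), function(p) {
      data.frame(patient = patient, period = p, q25 = qs[[p]][1],
                 median = qs[[p]][2], q75 = qs[[p]][3],
                 variation_pct = if (p == baseline || is.na(qs[[p]][2]) ||
                                     is.na(med_base)) NA_real_
                                 else variation_pct(qs[[p]][2], med_base))
    }))
  }
  out <- NULL
  if (grouping %in% c("both", "per_patient")) {
    for (sid in unique(dv$subject_id)) {
      sub <- dv[dv$subject_id == sid, ]
      vals <- lapply(stats::setNames(periods, periods),
                     function(p) sub$value[sub$period == p])
      out <- rbind(out, one_block(vals, sid))
    }
  }
  if (grouping %in% c("both", "pooled")) {
    vals <- lapply(stats::setNames(periods, periods),
                   function(p) dv$value[dv$period == p])
    out <- rbind(out, one_block(vals, "All"))
  }
  rownames(out) <- NULL
  out
}

#' Read a printed period-summary table fixture
#'
#' Parses the packaged transcriptions of the published period-summary tables
#' (continuous pain NRS; paroxysmal pain volume). The normalizer converts
#' European comma decimals ("3,5") to points and flags number-format
#' ambiguity: when any row of a patient violates the quantile ordering
#' `q25 <= median <= q75` under plain decimal parsing, the dot in that
#' patient's rows cannot be distinguished from a thousands separator, and
#' all of that patient's rows are marked `ambiguous_format` (this flags
#' exactly the volume rows of patient 01-01).
#'
#' @param table `"volume"` or `"nrs"`, or a path to a TSV laid out like the
#'   packaged fixtures.
#' @return The parsed data frame with numeric cells plus a per-row
#'   `ambiguous_format` logical.
#' @export
read_pain_table <- function(table = c("volume", "nrs")) {
  path <- if (file.exists(table[1])) {
    table[1]
  } else {
    table <- match.arg(table)
    system.file("extdata",
                if (table == "volume") "paroxysmal_volume_periods.tsv"
                else "continuous_pain_periods.tsv",
                package = "mibci", mustWork = TRUE)
  }
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  num_cols <- setdiff(names(raw), c("patient", "period"))
  for (cl in num_cols) {
    raw[[cl]] <- suppressWarnings(as.numeric(gsub(",", ".", raw[[cl]], fixed = TRUE)))
  }
  qsets <- if (all(c("q25", "med", "q75") %in% names(raw))) {
    list(c("q25", "med", "q75"))
  } else {
    list(c("min_q25", "min_med", "min_q75"), c("avg_q25", "avg_med", "avg_q75"),
         c("max_q25", "max_med", "max_q75"))
  }
  bad_row <- rep(FALSE, nrow(raw))
  for (qs in qsets) {
    bad_row <- bad_row |
      (raw[[qs[1]]] > raw[[qs[2]]] | raw[[qs[2]]] > raw[[qs[3]]])
  }
  bad_row[is.na(bad_row)] <- FALSE
  raw$ambiguous_format <- raw$patient %in% unique(raw$patient[bad_row])
  raw
}

# -- Mixed models -------------------------------------------------------------

# Build the modelling frame: subject, period level, daily response.
lmm_frame <- function(diary, response = c("volume_variation", "nrs_avg"),
                      baseline = "m-1") {
  response <- match.arg(response)
  if (response == "nrs_avg") {
    dv <- daily_values(diary, "nrs_avg")
    return(data.frame(subject = dv$subject_id, period = dv$period, y = dv$value))
  }
  dv <- daily_values(diary, "volume")
  out <- NULL
  for (sid in unique(dv$subject_id)) {
    sub <- dv[dv$subject_id == sid, ]
    base_med <- stats::median(sub$value[sub$period == baseline])
    if (!is.finite(base_med) || base_med == 0) {
      warning(sprintf("subject %s has zero/absent baseline median volume; excluded from the percent-variation model", sid))
      next
    }
    out <- rbind(out, data.frame(subject = sid, period = sub$period,
                                 y = 100 * (sub$value / base_med - 1)))
  }
  out
}

fit_period_model <- function(df, levels, per_patient = FALSE) {
  df <- df[df$period %in% levels, , drop = FALSE]
  df$period <- factor(df$period, levels = levels)
  assert_that(all(levels %in% df$period), "some period levels have no data")
  if (per_patient || length(unique(df$subject)) < 2) {
    if (!per_patient) {
      warning("single subject: fitting per-subject ordinary least squares instead of a mixed model")
    }
    res <- NULL
    for (sid in unique(df$subject)) {
      m <- stats::lm(y ~ period, data = df[df$subject == sid, ])
      cf <- summary(m)$coefficients
      terms <- grep("^period", rownames(cf), value = TRUE)
      res <- rbind(res, data.frame(
        subject = sid, term = sub("^period", "", terms),
        estimate = cf[terms, 1], se = cf[terms, 2],
        statistic = cf[terms, 3], p = cf[terms, 4], row.names = NULL))
    }
    return(structure(list(per_patient = res, levels = levels,
                          method = "per-subject OLS (Wald t)"),
                     class = "lmm_result"))
  }
  full <- lme4::lmer(y ~ period + (1 | subject), data = df, REML = TRUE)
  cf <- lme4::fixef(full)
  V <- as.matrix(stats::vcov(full))
  terms <- grep("^period", names(cf), value = TRUE)
  est <- cf[terms]
  se <- sqrt(diag(V)[terms])
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  vc <- as.data.frame(lme4::VarCorr(full))
  # LRT on the period fixed effect: both models refit with ML (an LRT of
  # fixed effects is not valid between REML fits)
  if (stats::var(df$y) < 1e-12) {
    # constant response: both fits are exact and the deviance difference is
    # numerically meaningless; the period effect is exactly null
    an <- data.frame(Chisq = c(NA, 0), Df = c(NA, length(levels) - 1),
                     `Pr(>Chisq)` = c(NA, 1), check.names = FALSE)
  } else {
    full_ml <- lme4::lmer(y ~ period + (1 | subject), data = df, REML = FALSE)
    null_ml <- lme4::lmer(y ~ 1 + (1 | subject), data = df, REML = FALSE)
    an <- stats::anova(null_ml, full_ml)
  }
  fixed <- data.frame(term = sub("^period", "", terms), estimate = est,
                      se = se, z = z, p = p,
                      ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
                      row.names = NULL)
  structure(list(fixed = fixed,
                 intercept = unname(cf["(Intercept)"]),
                 subject_var = vc$vcov[vc$grp == "subject"],
                 residual_var = vc$vcov[vc$grp == "Residual"],
                 lrt = list(statistic = max(0, an$Chisq[2]), df = an$Df[2],
                            p = an$`Pr(>Chisq)`[2]),
                 method = "REML", levels = levels, n = nrow(df),
                 model = full),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  if (!is.null(x$per_patient)) {
    cat("<lmm_result>", x$method, "\n")
    print(x$per_patient, digits = 4)
    return(invisible(x))
  }
  cat(sprintf("<lmm_result> random-intercept model (%s), n = %d, subject var %.3f\n",
              x$method, x$n, x$subject_var))
  print(x$fixed, digits = 4)
  cat(sprintf("LRT vs no-period model: chi^2(%d) = %.3f, p = %.4g\n",
              x$lrt$df, x$lrt$statistic, x$lrt$p))
  invisible(x)
}

#' Phase-level mixed model of a pain outcome
#'
#' Random-intercept linear mixed model of daily pain values on the study
#' phase, with three levels: pre-intervention (`m-1`, reference),
#' intervention (`w1w2` = weeks 1-2) and post-intervention (`w3w4` = weeks
#' 3-4). Estimated by REML; period contrasts are reported with Wald z tests
#' and 95% confidence intervals, and the global period effect with a
#' likelihood-ratio test of ML refits. The paroxysmal response is the daily
#' percent variation of pain volume from the subject's own baseline median;
#' the continuous-pain response is the raw daily average NRS. Long-term
#' follow-up periods (e.g. `w12-w23`) are never modelled — the switch from
#' daily to weekly self-assessment makes them incomparable — and are simply
#' absent from the phase map. With a single subject (or `per_patient =
#' TRUE`) per-subject ordinary least squares with Wald t tests is fitted
#' instead, matching the per-patient rows of the published contrast tables.
#'
#' @param diary A long diary (see [generate_pain_diaries()]).
#' @param response `"volume_variation"` (default) or `"nrs_avg"`.
#' @param phase_map Named character vector mapping diary periods to phase
#'   levels; defaults to `m-1, w1/w2 -> w1w2, w3/w4 -> w3w4`.
#' @param per_patient Fit per-subject OLS instead of the mixed model.
#' @return An `lmm_result`.
#' @export
fit_phase_lmm <- function(diary, response = c("volume_variation", "nrs_avg"),
                          phase_map = c("m-1" = "m-1", w1 = "w1w2", w2 = "w1w2",
                                        w3 = "w3w4", w4 = "w3w4"),
                          per_patient = FALSE) {
  df <- lmm_frame(diary, response)
  df <- df[df$period %in% names(phase_map), , drop = FALSE]
  df$period <- unname(phase_map[df$period])
  levels <- unique(unname(phase_map))
  fit_period_model(df, levels, per_patient)
}

#' Weekly mixed model of a pain outcome
#'
#' As [fit_phase_lmm()] but with a five-level period factor (`m-1`
#' reference, then `w1`-`w4`), giving one contrast per study week.
#'
#' @inheritParams fit_phase_lmm
#' @param weeks Period levels in order (first = reference).
#' @return An `lmm_result`.
#' @export
fit_weekly_lmm <- function(diary, response = c("volume_variation", "nrs_avg"),
                           weeks = c("m-1", "w1", "w2", "w3", "w4"),
                           per_patient = FALSE) {
  df <- lmm_frame(diary, response)
  df <- df[df$period %in% weeks, , drop = FALSE]
  fit_period_model(df, weeks, per_patient)
}
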