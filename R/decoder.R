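#' Fit the full CSP-LDA decoder on a labeled window set
#'
#' Fits the spatial filter bank and the linear discriminant on all supplied
#' windows (the "fit on the full open-loop dataset" step that follows a
#' passed cross-validation), recording the training accuracy and the
#' processing constants in the model metadata.
#'
#' @param ws A [labeled_windows()] set.
#' @param n_components CSP components (default 6).
#' @param band Band-pass interval the windows were filtered with, Hz
#'   (metadata; default `c(8, 30)`).
#' @param seed Optional integer recorded in the metadata.
#' @return Object of class `decoder_model`: `filter_bank`, `lda`,
#'   `class_labels`, `training_accuracy`, `metadata`.
#' @export
fit_decoder <- function(ws, n_components = 6, band = c(8, 30), seed = NULL) {
  bank <- fit_csp(ws, n_components)
  feats <- csp_features(ws, bank)
  lda <- fit_lda(feats, ws$labels)
  pred <- predict(lda, feats)
  structure(list(filter_bank = bank, lda = lda,
                 class_labels = lda$classes,
                 training_accuracy = mean(pred$labels == ws$labels),
                 metadata = list(band = band, window = ws$window_length,
                                 sfreq = ws$sfreq, n_components = n_components,
                                 seed = seed,
                                 fitted = format(Sys.time(), tz = "UTC"))),
            class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model> classes: %s | %d CSP components | training accuracy %.3f\n",
              paste(x$class_labels, collapse = "/"),
              x$filter_bank$n_components, x$training_accuracy))
  invisible(x)
}

#' Run-wise k-fold cross-validation of the CSP-LDA decoder
#'
#' The fold unit is the run/series, never the window: all windows of a run
#' stay in the same fold, so overlapping windows of one trial can never leak
#' between training and test. By default `k` equals the number of runs
#' (typically 9 for a competence test, 6 for a daily open-loop calibration).
#' Within each fold, CSP and LDA are fit on the training runs only. Accuracy
#' is the ratio of correct decisions to total decisions; optionally decisions
#' can be aggregated per trial by majority vote first.
#'
#' @param ws A [labeled_windows()] set with run provenance.
#' @param k `"auto"` (= number of runs) or an integer <= number of runs;
#'   runs are then grouped into `k` folds in run order.
#' @param n_components CSP components per fold model.
#' @param level `"window"` (default) scores every window decision;
#'   `"trial"` scores the modal label of each trial's windows.
#' @return Object of class `cv_report`: `fold_accuracies`, `mean_accuracy`,
#'   `k`, `fold_composition` (run ids per fold), `n_decisions`, `level`.
#' @export
cross_validate <- function(ws, k = "auto", n_components = 6,
                           level = c("window", "trial")) {
  stopifnot(inherits(ws, "labeled_windows"))
  level <- match.arg(level)
  runs <- sort(unique(ws$run_id))
  assert_that(length(runs) >= 2, "cross-validation needs at least 2 runs")
  classes <- canonical_classes(ws$labels)
  for (r in runs) {
    missing <- setdiff(classes, unique(ws$labels[ws$run_id == r]))
    if (length(missing) > 0) {
      stop2(sprintf("run %s is missing class(es): %s", r,
                    paste(missing, collapse = ", ")))
    }
  }
  if (identical(k, "auto")) k <- length(runs)
  assert_that(k >= 2 && k <= length(runs), "k must lie in [2, number of runs]")
  fold_of <- rep(seq_len(k), length.out = length(runs))[rank(runs)]
  folds <- split(runs, fold_of)

  acc <- numeric(k); ndec <- integer(k)
  for (f in seq_len(k)) {
    test_runs <- folds[[f]]
    tr <- ws_subset(ws, which(!(ws$run_id %in% test_runs)))
    te <- ws_subset(ws, which(ws$run_id %in% test_runs))
    bank <- fit_csp(tr, n_components)
    model <- fit_lda(csp_features(tr, bank), tr$labels)
    pred <- predict(model, csp_features(te, bank))
    if (level == "window") {
      acc[f] <- mean(pred$labels == te$labels)
      ndec[f] <- n_windows(te)
    } else {
      by_trial <- split(seq_len(n_windows(te)), te$trial_id)
      hits <- vapply(by_trial, function(ix) {
        modal <- names(which.max(table(factor(pred$labels[ix], levels = classes))))
        modal == te$labels[ix[1]]
      }, logical(1))
      acc[f] <- mean(hits)
      ndec[f] <- length(hits)
    }
  }
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc), k = k,
                 fold_composition = folds, n_decisions = ndec, level = level),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold (%s level): mean accuracy %.3f [folds: %s]\n",
              x$k, x$level, x$mean_accuracy,
              paste(sprintf("%.2f", x$fold_accuracies), collapse = " ")))
  invisible(x)
}

#' Competence gate decision
#'
#' Inclusion rule of the screening protocol: the mean cross-validated
#' accuracy must reach the threshold (>= 0.70; "reach" is inclusive, so
#' exactly 0.70 passes). The test may be attempted at most three times; a
#' fourth attempt is a protocol error.
#'
#' @param report A [cross_validate()] report.
#' @param threshold Gate threshold (default 0.70).
#' @param attempt Attempt number, 1-3.
#' @return A list `gate_decision`: `pass`, `mean_accuracy`, `threshold`,
#'   `attempt`.
#' @export
competence_gate <- function(report, threshold = 0.70, attempt = 1) {
  stopifnot(inherits(report, "cv_report"))
  if (!(attempt %in% 1:3)) {
    stop2("protocol error: at most three competence-test attempts are allowed")
  }
  structure(list(pass = report$mean_accuracy >= threshold,
                 mean_accuracy = report$mean_accuracy,
                 threshold = threshold, attempt = as.integer(attempt)),
            class = "gate_decision")
}

#' @export
print.gate_decision <- function(x, ...) {
  cat(sprintf("<gate_decision> attempt %d: accuracy %.3f %s threshold %.2f -> %s\n",
              x$attempt, x$mean_accuracy,
              if (x$mean_accuracy >= x$threshold) ">=" else "<",
              x$threshold, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' End-to-end open-loop calibration
#'
#' The full calibration chain on an annotated recording: band-pass filter,
#' epoch into 2-s windows over the 1-6 s post-cue span, reject outlier
#' windows, cross-validate run-wise, apply the competence gate, and — when
#' the gate passes — fit the deployable decoder on the full cleaned set.
#'
#' @param rec An annotated [eeg_recording()].
#' @param band Band-pass interval, Hz.
#' @param epoch_span,window,overlap See [epoch_and_window()].
#' @param z_max See [reject_outlier_windows()].
#' @param k,n_components See [cross_validate()].
#' @param threshold,attempt See [competence_gate()].
#' @return List: `model` (a `decoder_model`, or `NULL` if the gate failed),
#'   `cv`, `gate`, `rejection`.
#' @export
calibrate_decoder <- function(rec, band = c(8, 30), epoch_span = c(1, 6),
                              window = 2, overlap = 0.5, z_max = 3.5,
                              k = "auto", n_components = 6,
                              threshold = 0.70, attempt = 1) {
  filt <- bandpass_fir(rec, band[1], band[2])
  ws <- epoch_and_window(filt, epoch_span = epoch_span,
                         window = window, overlap = overlap)
  rej <- reject_outlier_windows(ws, z_max)
  cv <- cross_validate(rej$windows, k = k, n_components = n_components)
  gate <- competence_gate(cv, threshold, attempt)
  model <- if (gate$pass) fit_decoder(rej$windows, n_components, band) else NULL
  list(model = model, cv = cv, gate = gate, rejection = rej$report)
}

# -- Model persistence (JSON) -------------------------------------------------

#' Save / load a decoder model as JSON
#'
#' Lossless round-trip: matrices are serialized at full double precision, so
#' a reloaded model reproduces bit-identical predictions.
#'
#' @param model A `decoder_model`.
#' @param path File path.
#' @return `load_decoder` returns the `decoder_model`; `save_decoder`
#'   returns `path` invisibly.
#' @export
save_decoder <- function(model, path) {
  stopifnot(inherits(model, "decoder_model"))
  payload <- list(
    class_labels = model$class_labels,
    training_accuracy = model$training_accuracy,
    metadata = model$metadata,
    filter_bank = list(
      filters = model$filter_bank$filters,
      patterns = model$filter_bank$patterns,
      component_scores = model$filter_bank$component_scores,
      component_class = model$filter_bank$component_class,
      n_components = model$filter_bank$n_components,
      classes = model$filter_bank$classes,
      channel_names = model$filter_bank$channel_names),
    lda = list(means = model$lda$means, cov = model$lda$cov,
               classes = model$lda$classes, priors = model$lda$priors))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  fb <- p$filter_bank
  bank <- structure(list(filters = as.matrix(fb$filters),
                         patterns = as.matrix(fb$patterns),
                         component_scores = fb$component_scores,
                         component_class = fb$component_class,
                         eigenvalues = NULL,
                         n_components = fb$n_components,
                         classes = fb$classes,
                         channel_names = fb$channel_names),
                    class = "csp_bank")
  mu <- as.matrix(p$lda$means); rownames(mu) <- p$lda$classes
  Sw <- as.matrix(p$lda$cov)
  Si <- solve(Sw)
  pri <- stats::setNames(as.numeric(p$lda$priors), p$lda$classes)
  Wm <- Si %*% t(mu)
  b <- -0.5 * colSums(t(mu) * Wm) + log(pri)
  lda <- structure(list(means = mu, cov = Sw, cov_inv = Si,
                        classes = p$lda$classes, priors = pri,
                        weights = Wm, intercepts = b),
                   class = "lda_model")
  structure(list(filter_bank = bank, lda = lda,
                 class_labels = p$class_labels,
                 training_accuracy = p$training_accuracy,
                 metadata = p$metadata),
            class = "decoder_model")
}
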