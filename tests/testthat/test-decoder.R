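# deterministic toy window set with prescribed per-class channel variances
toy_windows <- function(sd_a = c(2, 1), sd_b = c(1, 2), n = 40, len = 100,
                        runs = 4) {
  withr::with_seed(99, {
    arr <- array(0, c(2 * n, 2, len))
    for (i in 1:n) arr[i, , ] <- rbind(rnorm(len, sd = sd_a[1]),
                                       rnorm(len, sd = sd_a[2]))
    for (i in (n + 1):(2 * n)) arr[i, , ] <- rbind(rnorm(len, sd = sd_b[1]),
                                                   rnorm(len, sd = sd_b[2]))
    labeled_windows(arr, rep(c("A", "B"), each = n), seq_len(2 * n),
                    rep(seq_len(runs), length.out = 2 * n), 2, 1, len / 2,
                    c("ch1", "ch2"))
  })
}

test_that("CSP solves the 2-channel variance-ratio toy exactly", {
  ws <- toy_windows()  # class A cov ~ diag(4,1), class B ~ diag(1,4)
  bank <- fit_csp(ws, 2)
  # oracle: per-channel one-vs-rest eigenvalue = var_A / (var_A + var_B)
  expect_equal(sort(bank$eigenvalues$A), c(0.2, 0.8), tolerance = 0.05)
  expect_equal(sort(bank$eigenvalues$B), c(0.2, 0.8), tolerance = 0.05)
  # filters align with the coordinate axes
  w <- bank$filters[1, ] / sqrt(sum(bank$filters[1, ]^2))
  expect_gt(max(abs(w)), 0.98)
  # patterns invert the filters on the retained subspace
  expect_lt(max(abs(bank$filters %*% bank$patterns - diag(2))), 1e-6)
})

test_that("classes with identical covariance give eigenvalues 1/2", {
  ws <- toy_windows(sd_a = c(1, 1), sd_b = c(1, 1), n = 60)
  bank <- fit_csp(ws, 2)
  expect_equal(unname(bank$eigenvalues$A), rep(0.5, 2), tolerance = 0.05)
})

test_that("CSP is scale-equivariant and needs two classes", {
  ws <- toy_windows()
  bank1 <- fit_csp(ws, 2)
  ws2 <- ws
  ws2$windows <- ws$windows * 7
  bank2 <- fit_csp(ws2, 2)
  # same directions (whitening absorbs the scale)
  cosang <- abs(sum(bank1$filters[1, ] * bank2$filters[1, ])) /
    sqrt(sum(bank1$filters[1, ]^2) * sum(bank2$filters[1, ]^2))
  expect_equal(cosang, 1, tolerance = 1e-9)
  ws1 <- mibci:::ws_subset(ws, which(ws$labels == "A"))
  expect_error(fit_csp(ws1, 2), "2 classes")
})

test_that("top CSP pattern localizes over the suppressed sensorimotor site", {
  ws <- ref_windows()
  bank <- fit_csp(ws)
  m <- standard_montage("standard19")
  for (cl in c("left_hand", "right_hand")) {
    target <- if (cl == "left_hand") "C4" else "C3"
    comp <- which(bank$component_class == cl)[1]
    peak_ch <- bank$channel_names[which.max(abs(bank$patterns[, comp]))]
    d <- acos(pmin(1, sum(m$positions[peak_ch, ] * m$positions[target, ])))
    expect_lt(d, 0.45)  # within ~2 electrode spacings of the target site
  }
})

test_that("log-variance features scale and floor as specified", {
  ws <- toy_windows(n = 10)
  bank <- fit_csp(ws, 2)
  f1 <- csp_features(ws, bank)
  ws2 <- ws
  ws2$windows[3, , ] <- ws$windows[3, , ] * 2
  f2 <- csp_features(ws2, bank)
  # doubling amplitude shifts log-variance by exactly log(4)
  expect_equal(f2[3, ], f1[3, ] + log(4), tolerance = 1e-12)
  expect_equal(f2[-3, ], f1[-3, ], tolerance = 1e-12)
  # zero window floors at log(eps) with a warning, no crash
  ws2$windows[1, , ] <- 0
  expect_warning(f3 <- csp_features(ws2, bank), "floored")
  expect_equal(unname(f3[1, ]), rep(log(1e-12), 2))
})

test_that("unit-variance noise through a near-identity filter gives features near 0", {
  ws <- toy_windows(sd_a = c(1, 1), sd_b = c(1, 1), n = 30)
  bank <- list(filters = diag(2), patterns = diag(2),
               component_scores = c(1, 1), component_class = c("A", "B"),
               eigenvalues = NULL, n_components = 2L,
               classes = c("A", "B"), channel_names = c("ch1", "ch2"))
  class(bank) <- "csp_bank"
  f <- csp_features(ws, bank)
  expect_lt(max(abs(colMeans(f))), 0.2)
})

test_that("LDA separates distant Gaussian clouds perfectly", {
  withr::with_seed(4, {
    X <- rbind(matrix(rnorm(200), 100, 2) + 5, matrix(rnorm(200), 100, 2) - 5)
  })
  lab <- rep(c("a", "b"), each = 100)
  m <- fit_lda(X, lab)
  pr <- predict(m, X)
  expect_equal(mean(pr$labels == lab), 1)
  # oracle: the distance-to-centroid classifier agrees everywhere
  cent <- rbind(colMeans(X[1:100, ]), colMeans(X[101:200, ]))
  oracle <- c("a", "b")[apply(X, 1, function(x) {
    which.min(colSums((t(cent) - x)^2))
  })]
  expect_equal(pr$labels, oracle)
  expect_equal(unname(rowSums(pr$posterior)), rep(1, 200), tolerance = 1e-9)
})

test_that("LDA direction matches the closed form and MASS::lda cross-check", {
  withr::with_seed(8, {
    S <- matrix(c(2, 0.8, 0.8, 1), 2)
    L <- chol(S)
    X <- rbind(matrix(rnorm(400), 200) %*% L,
               sweep(matrix(rnorm(400), 200) %*% L, 2, c(-3, 1)))
  })
  lab <- rep(c("a", "b"), each = 200)
  m <- fit_lda(X, lab)
  # closed form: boundary normal is Sigma^-1 (mu_a - mu_b)
  dir_closed <- m$cov_inv %*% (m$means["a", ] - m$means["b", ])
  dir_model <- m$weights[, "a"] - m$weights[, "b"]
  cosang <- sum(dir_closed * dir_model) /
    sqrt(sum(dir_closed^2) * sum(dir_model^2))
  expect_equal(cosang, 1, tolerance = 1e-6)
  # independent implementation agrees on labels
  skip_if_not_installed("MASS")
  mm <- MASS::lda(X, grouping = lab)
  expect_equal(as.character(predict(mm, X)$class), predict(m, X)$labels)
})

test_that("a point equidistant from both means has posterior 1/2", {
  withr::with_seed(14, {
    X <- rbind(matrix(rnorm(100), 50, 2) + 2, matrix(rnorm(100), 50, 2) - 2)
  })
  m <- fit_lda(X, rep(c("a", "b"), each = 50), priors = c(a = 0.5, b = 0.5))
  mid <- (m$means["a", ] + m$means["b", ]) / 2
  p <- predict(m, mid)$posterior
  expect_equal(unname(p[1, ]), c(0.5, 0.5), tolerance = 1e-9)
  # exact ties break toward the lowest class index: force perfect symmetry
  sym <- m
  sym$means <- rbind(a = c(1, 0), b = c(-1, 0))
  sym$cov_inv <- diag(2)
  sym$weights <- sym$cov_inv %*% t(sym$means)
  sym$intercepts <- -0.5 * colSums(t(sym$means) * sym$weights) + log(c(0.5, 0.5))
  expect_equal(predict(sym, c(0, 0))$labels, "a")
})

test_that("run-wise cross-validation uses runs as folds and reaches the gate", {
  ws <- ref_windows()
  cv <- cross_validate(ws, k = 9)
  expect_equal(cv$k, 9)
  expect_equal(unname(lengths(cv$fold_composition)), rep(1L, 9))
  expect_setequal(unlist(cv$fold_composition), 1:9)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies), tolerance = 1e-12)
  expect_gte(cv$mean_accuracy, 0.70)
  # trial-level variant is at least as coarse but consistent
  cvt <- cross_validate(ws, k = 9, level = "trial")
  expect_gte(cvt$mean_accuracy, cv$mean_accuracy - 0.05)
})

test_that("label permutation collapses accuracy to chance", {
  ws <- ref_windows()
  wsp <- ws
  wsp$labels <- withr::with_seed(11, sample(ws$labels))
  cvp <- cross_validate(wsp, k = 9)
  n <- sum(cvp$n_decisions)
  band <- 1 / 3 + c(-1.96, 1.96) * sqrt(1 / 3 * 2 / 3 / n)
  expect_gt(cvp$mean_accuracy, band[1] - 0.02)
  expect_lt(cvp$mean_accuracy, band[2] + 0.02)
})

test_that("channel-order shuffles leave accuracy unchanged", {
  s <- small_decoder()
  ws <- s$windows
  perm <- withr::with_seed(2, sample(length(ws$channel_names)))
  ws2 <- ws
  ws2$windows <- ws$windows[, perm, , drop = FALSE]
  ws2$channel_names <- ws$channel_names[perm]
  cv1 <- cross_validate(ws, k = 2)
  cv2 <- cross_validate(ws2, k = 2)
  expect_equal(cv1$fold_accuracies, cv2$fold_accuracies, tolerance = 1e-9)
})

test_that("accuracy grows with ERD depth in expectation", {
  acc <- sapply(c(0.1, 0.3, 0.5), function(d) {
    mean(sapply(1:3, function(s) {
      sess <- generate_mi_session(synth_eeg_config(erd_depth = d, n_series = 2,
                                                   seed = 300 + s))
      ws <- epoch_and_window(bandpass_fir(sess$recording))
      cross_validate(ws, k = 2)$mean_accuracy
    }))
  })
  expect_true(all(diff(acc) > -0.02))
})

test_that("runs missing a class are named in the error", {
  ws <- ref_windows()
  drop <- which(ws$run_id == 3 & ws$labels == "relax")
  ws2 <- mibci:::ws_subset(ws, setdiff(seq_len(n_windows(ws)), drop))
  expect_error(cross_validate(ws2, k = 9), "run 3.*relax")
})

test_that("competence gate is inclusive at 0.70 and caps attempts at three", {
  rep71 <- structure(list(fold_accuracies = rep(0.71, 9), mean_accuracy = 0.71,
                          k = 9, fold_composition = as.list(1:9),
                          n_decisions = rep(70, 9), level = "window"),
                     class = "cv_report")
  expect_true(competence_gate(rep71)$pass)
  rep70 <- rep71; rep70$mean_accuracy <- 0.70
  expect_true(competence_gate(rep70)$pass)
  rep69 <- rep71; rep69$mean_accuracy <- 0.699
  expect_false(competence_gate(rep69)$pass)
  expect_false(competence_gate(rep69, attempt = 3)$pass)
  expect_error(competence_gate(rep69, attempt = 4), "protocol error")
})

test_that("a saved decoder reloads to bit-identical predictions", {
  s <- small_decoder()
  feats <- csp_features(s$windows, s$model$filter_bank)
  p1 <- predict(s$model$lda, feats)
  path <- withr::local_tempfile(fileext = ".json")
  save_decoder(s$model, path)
  m2 <- load_decoder(path)
  p2 <- predict(m2$lda, csp_features(s$windows, m2$filter_bank))
  expect_identical(p1$labels, p2$labels)
  expect_equal(p1$posterior, p2$posterior, tolerance = 1e-12)
})
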