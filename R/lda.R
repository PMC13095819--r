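## Pooled-covariance Linear Discriminant Analysis with closed-form posteriors.

#' Fit a linear discriminant classifier
#'
#' Classic LDA: class means with a pooled within-class covariance, giving the
#' linear discriminant functions
#' `delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k`
#' and softmax posteriors. The pooled covariance is shrunk toward its
#' diagonal mean automatically when ill-conditioned. Class priors default to
#' the empirical proportions.
#'
#' @param features Numeric matrix, samples x features.
#' @param labels Class label per row; >= 2 classes with >= 2 samples each.
#' @param priors Optional named prior probabilities (default empirical).
#' @return Object of class `lda_model` with `means`, `cov_inv`, `classes`,
#'   `priors`, `weights` (discriminant slopes) and `intercepts`.
#' @export
fit_lda <- function(features, labels, priors = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- canonical_classes(labels)
  assert_that(length(classes) >= 2, "LDA needs at least 2 classes")
  counts <- table(labels)
  assert_that(all(counts >= 2), "every class needs at least 2 samples")
  p <- ncol(features)
  mu <- t(vapply(classes, function(cl) colMeans(features[labels == cl, , drop = FALSE]),
                 numeric(p)))
  Sw <- matrix(0, p, p)
  for (cl in classes) {
    X <- features[labels == cl, , drop = FALSE]
    Xc <- sweep(X, 2, mu[cl, ])
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (nrow(features) - length(classes))
  Sw <- shrink_cov(Sw)
  Si <- solve(Sw)
  pri <- priors %||% (as.numeric(counts[classes]) / length(labels))
  names(pri) <- classes
  Wm <- Si %*% t(mu)                               # p x K slopes
  b <- -0.5 * colSums(t(mu) * Wm) + log(pri)       # intercepts
  structure(list(means = mu, cov = Sw, cov_inv = Si, classes = classes,
                 priors = pri, weights = Wm, intercepts = b),
            class = "lda_model")
}

#' Predict classes and posteriors from a fitted LDA
#'
#' Posteriors sum to one; exact posterior ties are broken deterministically
#' in favor of the lowest class index.
#'
#' @param object An `lda_model`.
#' @param features Samples x features matrix (or a single feature vector).
#' @param ... Unused.
#' @return List with `labels` (character) and `posterior`
#'   (samples x classes matrix, columns in `object$classes` order).
#' @export
predict.lda_model <- function(object, features, ...) {
  features <- if (is.null(dim(features))) matrix(features, nrow = 1) else as.matrix(features)
  D <- features %*% object$weights
  D <- sweep(D, 2, object$intercepts, `+`)
  D <- D - apply(D, 1, max)
  P <- exp(D)
  P <- P / rowSums(P)
  colnames(P) <- object$classes
  idx <- apply(P, 1, which.max)  # which.max: first max -> lowest class index
  list(labels = object$classes[idx], posterior = P)
}
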