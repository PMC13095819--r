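## Common Spatial Patterns: supervised spatial filtering that maximizes the
## variance ratio between a class and the rest via a generalized eigenproblem.

# Canonical class ordering used everywhere: the three motor-imagery states in
# protocol order first, anything else alphabetical after them.
canonical_classes <- function(labels) {
  fixed <- c("relax", "left_hand", "right_hand")
  u <- unique(labels)
  c(fixed[fixed %in% u], sort(setdiff(u, fixed)))
}

# Moore-Penrose pseudo-inverse via SVD (no external dependency).
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Ledoit-Wolf-style diagonal shrinkage, escalated until well conditioned.
shrink_cov <- function(C, max_cond = 1e8) {
  target <- mean(diag(C)) * diag(nrow(C))
  gamma <- 0
  repeat {
    Cs <- (1 - gamma) * C + gamma * target
    k <- tryCatch(kappa(Cs, exact = TRUE), error = function(e) Inf)
    if (is.finite(k) && k <= max_cond) return(Cs)
    gamma <- if (gamma == 0) 1e-6 else gamma * 10
    if (gamma > 1) return(target)
  }
}

# Mean per-window sample covariance of the windows with the given indices.
class_covariance <- function(ws, rows) {
  p <- dim(ws$windows)[2]
  C <- matrix(0, p, p)
  for (i in rows) {
    X <- ws$windows[i, , , drop = TRUE]
    X <- X - rowMeans(X)
    C <- C + tcrossprod(X) / (ncol(X) - 1)
  }
  C / length(rows)
}

#' Fit a CSP spatial filter bank
#'
#' One-vs-rest Common Spatial Patterns for two or more classes. For each
#' class the generalized eigenproblem of (class covariance, class + rest
#' covariance) is solved by whitening; eigenvalues lie in `[0, 1]` and
#' measure the fraction of band-limited variance the class explains along
#' each filter (0.5 = no discrimination). Filters are ranked per class by
#' eigenvalue extremeness `2 |lambda - 1/2|` and retained round-robin across
#' classes (near-duplicate directions skipped) up to `n_components`. Spatial
#' patterns — the scalp maps of the retained components — come from the
#' inverse of each decomposition's full filter matrix (equivalently
#' `Ct %*% w` for a whitening-based solution), so each column shows the
#' topography of the source its filter extracts; `t(W[j, ]) %*% A[, j] = 1`
#' for every retained component.
#'
#' @param ws A [labeled_windows()] set with >= 2 classes; each class needs at
#'   least `channels / 4` windows (conditioning guard).
#' @param n_components Number of retained filters (default 6).
#' @return Object of class `csp_bank`: `filters` (components x channels),
#'   `patterns` (channels x components), `component_scores`,
#'   `component_class`, `eigenvalues` (per one-vs-rest problem), `classes`,
#'   `channel_names`.
#' @export
fit_csp <- function(ws, n_components = 6) {
  stopifnot(inherits(ws, "labeled_windows"))
  classes <- canonical_classes(ws$labels)
  assert_that(length(classes) >= 2, "CSP needs at least 2 classes")
  p <- dim(ws$windows)[2]
  counts <- table(ws$labels)
  assert_that(all(counts >= max(2, ceiling(p / 4))),
              "too few windows per class for a stable covariance (need >= channels/4)")
  assert_that(n_components <= p, "n_components cannot exceed channel count")

  covs <- lapply(classes, function(cl) {
    shrink_cov(class_covariance(ws, which(ws$labels == cl)))
  })
  names(covs) <- classes

  per_class <- lapply(classes, function(cl) {
    C1 <- covs[[cl]]
    others <- setdiff(classes, cl)
    C2 <- Reduce(`+`, covs[others]) / length(others)
    Ct <- shrink_cov(C1 + C2)
    e <- eigen(Ct, symmetric = TRUE)
    keep <- e$values > max(e$values) * 1e-12
    W0 <- t(e$vectors[, keep, drop = FALSE]) / sqrt(e$values[keep])
    S <- W0 %*% C1 %*% t(W0)
    S <- (S + t(S)) / 2
    es <- eigen(S, symmetric = TRUE)
    Wc <- t(es$vectors) %*% W0         # rows = filters, ordered by lambda desc
    lam <- pmin(1, pmax(0, es$values))
    sc <- 2 * abs(lam - 0.5)
    o <- order(sc, decreasing = TRUE)
    # spatial patterns of this decomposition: the inverse of the full filter
    # matrix, which for a whitening-based solution equals Ct w per filter —
    # the scalp topography of the extracted source
    Ap <- Ct %*% t(Wc)
    list(filters = Wc[o, , drop = FALSE], patterns = Ap[, o, drop = FALSE],
         lambda = lam[o], score = sc[o], eigenvalues = lam)
  })
  names(per_class) <- classes

  # round-robin retention across classes, skipping near-duplicate directions
  W <- matrix(0, 0, p)
  A <- matrix(0, p, 0)
  score <- numeric(0); comp_class <- character(0)
  ptr <- stats::setNames(rep(1L, length(classes)), classes)
  while (nrow(W) < n_components) {
    advanced <- FALSE
    for (cl in classes) {
      if (nrow(W) >= n_components) break
      pc <- per_class[[cl]]
      while (ptr[cl] <= nrow(pc$filters)) {
        w <- pc$filters[ptr[cl], ]
        i <- ptr[cl]; ptr[cl] <- ptr[cl] + 1L
        dup <- FALSE
        if (nrow(W) > 0) {
          cosang <- abs(W %*% w) / (sqrt(rowSums(W^2)) * sqrt(sum(w^2)))
          dup <- any(cosang > 0.999)
        }
        if (!dup) {
          W <- rbind(W, w)
          A <- cbind(A, pc$patterns[, i])
          score <- c(score, pc$score[i]); comp_class <- c(comp_class, cl)
          advanced <- TRUE
          break
        }
      }
    }
    if (!advanced) break  # every candidate exhausted
  }
  rownames(W) <- NULL
  dimnames(A) <- list(ws$channel_names, NULL)

  structure(list(filters = W, patterns = A, component_scores = score,
                 component_class = comp_class,
                 eigenvalues = lapply(per_class, `[[`, "eigenvalues"),
                 n_components = nrow(W), classes = classes,
                 channel_names = ws$channel_names),
            class = "csp_bank")
}

#' @export
print.csp_bank <- function(x, ...) {
  cat(sprintf("<csp_bank> %d components over %d channels; scores: %s\n",
              x$n_components, length(x$channel_names),
              paste(sprintf("%.2f", x$component_scores), collapse = ", ")))
  invisible(x)
}

# log-variance features of one channels-x-samples matrix under a filter bank
log_var_features <- function(X, W, eps = 1e-12) {
  Y <- W %*% X
  v <- apply(Y, 1, stats::var)
  log(pmax(v, eps))
}

#' CSP log-variance features
#'
#' `feature[i, j] = log(var(filter_j %*% window_i))` — the standard CSP
#' feature map. Constant (zero-variance) windows are floored at
#' `log(1e-12)` with a warning rather than producing `-Inf`.
#'
#' @param ws A [labeled_windows()] set.
#' @param bank A [fit_csp()] filter bank fit on the same channel set.
#' @return Numeric matrix, windows x components.
#' @export
csp_features <- function(ws, bank) {
  stopifnot(inherits(ws, "labeled_windows"), inherits(bank, "csp_bank"))
  assert_that(identical(ws$channel_names, bank$channel_names),
              "window channels do not match the filter bank")
  n <- n_windows(ws)
  F <- matrix(0, n, bank$n_components)
  floored <- FALSE
  for (i in seq_len(n)) {
    f <- log_var_features(ws$windows[i, , , drop = TRUE], bank$filters)
    if (any(f <= log(1e-12))) floored <- TRUE
    F[i, ] <- f
  }
  if (floored) warning("constant window(s): log-variance floored at log(1e-12)")
  F
}
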