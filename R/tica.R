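# Time-lagged independent component analysis: the generalized eigenproblem
# C^tl(tau) U = C U Lambda on the instantaneous and time-lagged covariance
# matrices of the feature time series. Eigenvectors with the largest
# eigenvalues are the slowest linear coordinates of the dynamics.

# Normalize feature input to a bare list of numeric matrices.
feature_matrices <- function(features) {
  if (inherits(features, "feature_set")) return(features$values)
  if (is.matrix(features)) return(list(features))
  if (is.list(features) && all(vapply(features, is.matrix, logical(1)))) {
    return(features)
  }
  stopf("features must be a feature_set, a matrix, or a list of matrices")
}

#' Estimate a tICA model
#'
#' Computes the instantaneous covariance `C = <x(t) x(t)^T>` and the
#' time-lagged covariance `C^tl(tau) = <x(t) x(t+tau)^T>` on mean-centered
#' data (lagged pairs never cross trajectory boundaries), symmetrizes
#' `C^tl`, and solves the generalized eigenproblem
#' `C^tl U = C U Lambda` with a small ridge added to the diagonal of `C`
#' (binary contact columns make `C` rank-deficient). Components are sorted by
#' descending eigenvalue; each eigenvector's largest-magnitude entry is made
#' positive so results are deterministic.
#'
#' @param features A `feature_set`, a matrix, or a list of matrices
#'   (frames x descriptors).
#' @param lag Lag time in frames (>= 1, shorter than every trajectory).
#' @param n_components Number of components retained (default 10).
#' @param ridge Ridge added to `diag(C)`; default `1e-8 * mean(diag(C))`.
#' @return Object of class `tica_model` with elements `mean`, `C`, `Ctl`,
#'   `U` (d x n_components, C-orthonormal), `lambda` (all eigenvalues,
#'   descending), `lag`, `n_components`, `frame_interval_ns`.
#' @export
estimate_tica <- function(features, lag, n_components = 10, ridge = NULL) {
  xs <- feature_matrices(features)
  dt <- if (inherits(features, "feature_set")) features$frame_interval_ns else NA_real_
  if (!is_count(lag)) stopf("lag must be a positive integer")
  nf <- vapply(xs, nrow, integer(1))
  if (any(nf <= lag)) {
    stopf("lag (%d) must be shorter than every trajectory (min length %d)",
          lag, min(nf))
  }
  d <- ncol(xs[[1]])
  if (n_components > d) stopf("n_components exceeds feature dimension")
  ntot <- sum(nf)
  mu <- Reduce(`+`, lapply(xs, colSums)) / ntot
  C <- matrix(0, d, d); Ctl <- matrix(0, d, d)
  npairs <- 0
  for (x in xs) {
    xc <- sweep(x, 2, mu)
    C <- C + crossprod(xc)
    n <- nrow(xc)
    a <- xc[1:(n - lag), , drop = FALSE]
    b <- xc[(1 + lag):n, , drop = FALSE]
    Ctl <- Ctl + crossprod(a, b)
    npairs <- npairs + (n - lag)
  }
  C <- C / ntot
  Ctl <- Ctl / npairs
  Ctl <- (Ctl + t(Ctl)) / 2
  if (is.null(ridge)) ridge <- 1e-8 * sum(diag(C)) / d
  Cr <- C + diag(ridge, d)
  R <- tryCatch(chol(Cr), error = function(e) {
    stopf("covariance matrix singular even after ridge %.3g; increase ridge", ridge)
  })
  Rinv <- backsolve(R, diag(d))
  M <- t(Rinv) %*% Ctl %*% Rinv
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  U <- Rinv %*% e$vectors
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  lambda <- e$values
  if (max(abs(lambda)) > 1 + 1e-6) {
    warnf("tICA eigenvalue exceeds 1 (%.6f); check lag and sampling",
          max(abs(lambda)))
  }
  rownames(U) <- colnames(xs[[1]])
  structure(list(mean = mu, C = C, Ctl = Ctl,
                 U = U[, seq_len(n_components), drop = FALSE],
                 lambda = lambda, lag = lag, n_components = n_components,
                 ridge = ridge, frame_interval_ns = dt),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tica_model: %d features -> %d components, lag %d frames\n",
              nrow(x$U), x$n_components, x$lag))
  cat("leading eigenvalues:",
      paste(sprintf("%.4f", utils::head(x$lambda, x$n_components)),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.tica_model <- function(object, ...) {
  lam <- utils::head(object$lambda, object$n_components)
  ts <- -object$lag / log(pmin(abs(lam), 1 - 1e-12))
  out <- data.frame(component = seq_along(lam), eigenvalue = lam,
                    timescale_frames = ts)
  if (!is.na(object$frame_interval_ns)) {
    out$timescale_ns <- ts * object$frame_interval_ns
  }
  out
}

#' Project features onto tICA components
#'
#' Mean-centers the data with the model's mean and multiplies into the
#' retained eigenvectors. Projections of the training data have unit variance
#' per component (C-orthonormality).
#'
#' @param object A `tica_model`.
#' @param features A `feature_set`, matrix, or list of matrices with the
#'   model's feature dimension.
#' @param ... Unused.
#' @return A list of `n_frames x n_components` matrices (one per
#'   trajectory), or a single matrix if a matrix was given.
#' @export
predict.tica_model <- function(object, features, ...) {
  xs <- feature_matrices(features)
  single <- is.matrix(features)
  out <- lapply(xs, function(x) {
    if (ncol(x) != length(object$mean)) {
      stopf("feature dimension %d does not match model (%d)",
            ncol(x), length(object$mean))
    }
    sweep(x, 2, object$mean) %*% object$U
  })
  if (single) out[[1]] else out
}

#' Rank descriptors by correlation with a tICA component
#'
#' Pearson correlation of each descriptor time series with the projection
#' onto one component, ranked by absolute value. This identifies the
#' structural descriptors most involved in a slow degree of freedom.
#'
#' @param projection Output of [predict.tica_model()] on the same data.
#' @param features The feature input used for the projection.
#' @param component Component index (default 1).
#' @param top_n Rows returned (default 75).
#' @return Data frame with `descriptor`, `correlation`, `abs_correlation`,
#'   `constant` (flag for zero-variance descriptors, reported as 0).
#' @export
rank_descriptor_correlations <- function(projection, features, component = 1,
                                         top_n = 75) {
  xs <- feature_matrices(features)
  ps <- if (is.matrix(projection)) list(projection) else projection
  if (length(xs) != length(ps)) stopf("projection and features disagree in trajectory count")
  x <- do.call(rbind, xs)
  p <- do.call(rbind, ps)[, component]
  if (nrow(x) != length(p)) stopf("frame counts differ between projection and features")
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0
  cors <- rep(0, ncol(x))
  cors[!const] <- as.numeric(stats::cor(x[, !const, drop = FALSE], p))
  nm <- colnames(x)
  if (is.null(nm)) nm <- sprintf("d%d", seq_len(ncol(x)))
  out <- data.frame(descriptor = nm, correlation = cors,
                    abs_correlation = abs(cors), constant = const,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abs_correlation), ]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
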