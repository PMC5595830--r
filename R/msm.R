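# Markov state model estimation: k-means microstates in tICA space,
# sliding-window transition counts, reversible maximum-likelihood transition
# matrix, implied timescales, Chapman-Kolmogorov validation.

#' Discretize projected frames into microstates with k-means
#'
#' Pools the projected frames of all trajectories, seeds k-means++ centers
#' with a dedicated RNG stream, and runs Lloyd/Hartigan-Wong refinement.
#' Deterministic per seed.
#'
#' @param projections List of `n_frames x n_components` matrices (output of
#'   [predict.tica_model()]) or a single matrix.
#' @param k Number of microstates (the receptor analyses use 1000).
#' @param seed Integer seed.
#' @param iter_max Maximum k-means iterations.
#' @return Object of class `microstate_assignment`: list with `labels` (one
#'   integer vector per trajectory, values 1..k), `k`, `centers`.
#' @export
cluster_microstates <- function(projections, k = 1000, seed = 1L,
                                iter_max = 100L) {
  ps <- if (is.matrix(projections)) list(projections) else projections
  pool <- do.call(rbind, ps)
  if (nrow(pool) < k) stopf("fewer frames (%d) than microstates (%d)", nrow(pool), k)
  centers <- with_rng_seed(seed, kmeanspp_seed(pool, k))
  km <- suppressWarnings(stats::kmeans(pool, centers = centers,
                                       iter.max = iter_max))
  nf <- vapply(ps, nrow, integer(1))
  ends <- cumsum(nf)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  labels <- lapply(seq_along(ps), function(i) km$cluster[starts[i]:ends[i]])
  structure(list(labels = labels, k = k, centers = km$centers, seed = seed),
            class = "microstate_assignment")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center. Duplicated points get probability 0
# once covered, so centers are distinct whenever k <= number of distinct rows.
kmeanspp_seed <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 <= 0)) {
      # all points covered: re-seed from the farthest (duplicated) points
      i <- which.max(d2)
    } else {
      i <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    centers[j + 1L, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[i, ])^2))
  }
  centers
}

#' @export
print.microstate_assignment <- function(x, ...) {
  cat(sprintf("microstate_assignment: %d trajectories, k = %d\n",
              length(x$labels), x$k))
  invisible(x)
}

assignment_labels <- function(assignment) {
  if (inherits(assignment, "microstate_assignment")) return(assignment$labels)
  if (is.list(assignment)) return(assignment)
  list(as.integer(assignment))
}

# Sliding-window transition counts at a lag, over a list of label vectors.
count_transitions <- function(labels, lag, K) {
  C <- matrix(0, K, K)
  for (s in labels) {
    n <- length(s)
    if (n <= lag) next
    from <- s[1:(n - lag)]
    to <- s[(1 + lag):n]
    idx <- (from - 1L) * K + to
    C <- C + matrix(tabulate(idx, K * K), K, K, byrow = TRUE)
  }
  C
}

# Reversible maximum-likelihood transition matrix via the self-consistent
# fixed-point iteration on the symmetric flow variables x_ij:
#   x_ij <- (c_ij + c_ji) / (c_i / x_i + c_j / x_j)
# converged when the largest relative change drops below tol.
reversible_mle <- function(C, tol = 1e-10, max_iter = 1e6) {
  K <- nrow(C)
  ci <- rowSums(C)
  if (any(ci == 0)) stopf("state without outgoing counts; trim to the ergodic set first")
  Csym <- C + t(C)
  sym <- which(Csym > 0)
  X <- Csym
  for (it in seq_len(max_iter)) {
    xi <- rowSums(X)
    q <- ci / xi
    denom <- outer(q, q, "+")
    Xn <- Csym / denom  # zero stays zero where Csym is zero
    delta <- max(abs(Xn[sym] - X[sym]) / X[sym])
    X <- Xn
    if (delta < tol) {
      Tm <- X / rowSums(X)
      pi <- rowSums(X) / sum(X)
      return(list(T = Tm, pi = pi, iterations = it, delta = delta))
    }
  }
  stopf("reversible MLE did not converge in %d iterations (last change %.3g)",
        max_iter, delta)
}

#' Estimate a reversible Markov state model
#'
#' Counts sliding-window transitions at the lag, restricts to the largest
#' strongly connected set of states, and estimates the transition matrix by
#' maximum likelihood under the detailed-balance constraint. The stationary
#' distribution comes from the reversible estimate; the spectrum is obtained
#' from the symmetrized matrix, so eigenvalues are real.
#'
#' @param assignment A `microstate_assignment`, or a list of integer label
#'   vectors (one per trajectory, states 1..K).
#' @param lag Lag time in frames.
#' @param frame_interval_ns Physical time per frame, used to report lag and
#'   timescales in nanoseconds (optional).
#' @return Object of class `markov_model`: `T` (row-stochastic), `pi`,
#'   `counts` (restricted), `active` (original state labels of the ergodic
#'   set), `lambda` (real eigenvalues, descending), `psi` (right
#'   eigenvectors), `lag_frames`, `frame_interval_ns`.
#' @export
estimate_msm <- function(assignment, lag, frame_interval_ns = NULL) {
  labels <- assignment_labels(assignment)
  if (!is_count(lag)) stopf("lag must be a positive integer")
  K <- max(unlist(lapply(labels, max)))
  C <- count_transitions(labels, lag, K)
  if (sum(C) == 0) stopf("no transitions observed at lag %d", lag)
  g <- igraph::graph_from_adjacency_matrix(C > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  # keep components that actually carry counts, then the largest
  sizes <- tabulate(comp$membership, comp$no)
  weight <- vapply(seq_len(comp$no), function(m) {
    idx <- which(comp$membership == m)
    sum(C[idx, idx])
  }, numeric(1))
  # choose the component with most states; break ties by intra-component counts
  best <- order(-sizes, -weight)[1]
  active <- sort(which(comp$membership == best))
  if (length(active) < K) {
    warnf("restricting to largest strongly connected set: %d of %d states",
          length(active), K)
  }
  Ca <- C[active, active, drop = FALSE]
  if (length(active) == 1L) {
    fit <- list(T = matrix(1, 1, 1), pi = 1, iterations = 0L)
  } else {
    fit <- reversible_mle(Ca)
  }
  Tm <- fit$T; pi <- fit$pi
  db <- abs(pi * Tm - t(pi * Tm))
  if (max(db) > 1e-8 * max(pi * Tm)) {
    stopf("detailed balance violated after MLE (max deviation %.3g)", max(db))
  }
  # spectrum of the pi-symmetrized matrix: real, sorted descending
  s <- sqrt(pi)
  S <- (s * Tm) %*% diag(1 / s, length(pi))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  psi <- diag(1 / s, length(pi)) %*% e$vectors
  structure(list(T = Tm, pi = pi, counts = Ca, active = active,
                 lambda = e$values, psi = psi,
                 n_states = length(active), lag_frames = lag,
                 frame_interval_ns = frame_interval_ns,
                 mle_iterations = fit$iterations),
            class = "markov_model")
}

#' Build a Markov model from a known transition matrix
#'
#' Wraps an explicitly specified row-stochastic matrix as a `markov_model`,
#' with the stationary distribution and spectrum computed from it. Useful
#' for transition-path and evolution analyses of chains with known
#' transition probabilities. A warning is issued if the chain does not
#' satisfy detailed balance (the spectrum is then taken as the real part of
#' the eigenvalues).
#'
#' @param T Row-stochastic square matrix.
#' @param lag_frames Lag the matrix refers to (default 1 frame).
#' @param frame_interval_ns Optional physical frame interval.
#' @return A `markov_model`.
#' @export
as_markov_model <- function(T, lag_frames = 1L, frame_interval_ns = NULL) {
  check_prob_matrix(T, tol = 1e-10)
  pi <- stationary_distribution(T)
  flow <- pi * T
  irreducible <- min(pi) > 1e-12
  reversible <- irreducible && max(abs(flow - t(flow))) <= 1e-8 * max(flow)
  if (!irreducible) {
    warnf("chain is not irreducible: some states have zero stationary probability")
  }
  if (reversible) {
    s <- sqrt(pi)
    S <- (s * T) %*% diag(1 / s, length(pi))
    S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    lambda <- e$values
    psi <- diag(1 / s, length(pi)) %*% e$vectors
  } else {
    if (irreducible) {
      warnf("transition matrix is not reversible; spectrum may be complex (real parts kept)")
    }
    e <- eigen(T)
    ord <- order(-Re(e$values))
    lambda <- Re(e$values)[ord]
    psi <- Re(e$vectors)[, ord, drop = FALSE]
  }
  structure(list(T = T, pi = pi, counts = NULL, active = seq_len(nrow(T)),
                 lambda = lambda, psi = psi, n_states = nrow(T),
                 lag_frames = as.integer(lag_frames),
                 frame_interval_ns = frame_interval_ns,
                 mle_iterations = NA_integer_),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("markov_model: %d states, lag %d frames%s\n",
              x$n_states, x$lag_frames,
              if (!is.null(x$frame_interval_ns))
                sprintf(" (%g ns)", x$lag_frames * x$frame_interval_ns) else ""))
  lam <- utils::head(x$lambda, 5)
  cat("leading eigenvalues:", paste(sprintf("%.4f", lam), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.markov_model <- function(object, ...) {
  ts <- implied_ts_from_lambda(object$lambda, object$lag_frames)
  data.frame(mode = seq_along(object$lambda),
             eigenvalue = object$lambda,
             timescale_frames = ts,
             stationary_max = c(max(object$pi), rep(NA, length(object$lambda) - 1)))
}

# Implied timescale t_i = -tau / ln|lambda_i| (lambda_1 = 1 -> NA; |lambda|
# at or above 1 within tolerance -> Inf).
implied_ts_from_lambda <- function(lambda, lag, tol = 1e-12) {
  out <- rep(NA_real_, length(lambda))
  for (i in seq_along(lambda)) {
    al <- abs(lambda[i])
    if (i == 1) next
    out[i] <- if (al >= 1 - tol) Inf else -lag / log(al)
  }
  out
}

#' Implied timescale curves over a set of lags
#'
#' Estimates an MSM at each lag and converts eigenvalues to relaxation
#' timescales `t_i = -tau / ln|lambda_i|`. Markovian dynamics give curves
#' that are flat in the lag. Optional trajectory bootstrap adds first/third
#' quartiles.
#'
#' @param assignment `microstate_assignment` or list of label vectors.
#' @param lags Integer vector of lags (frames).
#' @param n_timescales Number of timescales reported per lag.
#' @param frame_interval_ns Optional physical frame interval.
#' @param bootstrap Optional list with `n_samples`, `fraction`, `seed`
#'   (defaults 100, 0.95, 1) enabling quartile estimation.
#' @return Data frame of class `implied_timescales`: lag, index, timescale
#'   (frames; `Inf` flagged via `infinite`), optional `q1`, `q3`, and
#'   physical-unit columns when `frame_interval_ns` is given.
#' @export
implied_timescales <- function(assignment, lags, n_timescales = 2,
                               frame_interval_ns = NULL, bootstrap = NULL) {
  labels <- assignment_labels(assignment)
  shortest <- min(vapply(labels, length, integer(1)))
  if (any(lags >= shortest)) stopf("every lag must be shorter than the shortest trajectory")
  rows <- list()
  for (lag in lags) {
    m <- estimate_msm(labels, lag)
    ts <- implied_ts_from_lambda(m$lambda, lag)[1 + seq_len(n_timescales)]
    q1 <- q3 <- rep(NA_real_, n_timescales)
    if (!is.null(bootstrap)) {
      bs <- utils::modifyList(list(n_samples = 100, fraction = 0.95, seed = 1),
                              bootstrap)
      est <- function(trajs) {
        mm <- suppressWarnings(estimate_msm(trajs, lag))
        implied_ts_from_lambda(mm$lambda, lag)[1 + seq_len(n_timescales)]
      }
      b <- bootstrap_trajectories(est, labels, n_samples = bs$n_samples,
                                  fraction = bs$fraction, seed = bs$seed)
      q1 <- b$q1; q3 <- b$q3
    }
    rows[[length(rows) + 1L]] <- data.frame(
      lag_frames = lag, index = seq_len(n_timescales) + 1L,
      timescale_frames = ts, q1_frames = q1, q3_frames = q3,
      infinite = !is.finite(ts))
  }
  out <- do.call(rbind, rows)
  if (!is.null(frame_interval_ns)) {
    out$lag_ns <- out$lag_frames * frame_interval_ns
    out$timescale_ns <- out$timescale_frames * frame_interval_ns
  }
  class(out) <- c("implied_timescales", class(out))
  out
}

#' Chapman-Kolmogorov test on macrostate sets
#'
#' Compares, for increasing multiples of the model lag, the probability of
#' remaining in a given set of microstates as predicted by powers of the
#' transition matrix against the probability re-estimated directly from the
#' trajectories at the longer lag.
#'
#' @param model A `markov_model`.
#' @param assignment The assignment the model was estimated from.
#' @param sets List of disjoint integer vectors of microstate labels.
#' @param multiples Integer multiples of the model lag (include 1).
#' @param bootstrap Optional list (`n_samples`, `fraction`, `seed`) for
#'   quartiles on the observed values.
#' @return Data frame of class `ck_test`: set, multiple, predicted, observed
#'   (+ quartiles).
#' @export
ck_test <- function(model, assignment, sets, multiples = 1:5,
                    bootstrap = NULL) {
  labels <- assignment_labels(assignment)
  if (length(sets) > 1) {
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (i < j && length(intersect(sets[[i]], sets[[j]])))
          stopf("macrostate sets must be disjoint")
      }
    }
  }
  shortest <- min(vapply(labels, length, integer(1)))
  if (max(multiples) * model$lag_frames >= shortest) {
    stopf("largest multiple exceeds trajectory length")
  }
  self_prob <- function(m, set) {
    idx <- match(intersect(set, m$active), m$active)
    if (length(idx) == 0L) return(NA_real_)
    w <- m$pi[idx] / sum(m$pi[idx])
    sum(w * rowSums(m$T[idx, idx, drop = FALSE]))
  }
  rows <- list()
  for (si in seq_along(sets)) {
    set <- sets[[si]]
    Tp <- diag(model$n_states)
    for (mult in sort(unique(multiples))) {
      # predicted from T^mult restricted to the set
      Tm <- model$T
      Tpow <- Tm
      if (mult > 1) for (i in seq_len(mult - 1)) Tpow <- Tpow %*% Tm
      idx <- match(intersect(set, model$active), model$active)
      w <- model$pi[idx] / sum(model$pi[idx])
      predicted <- sum(w * rowSums(Tpow[idx, idx, drop = FALSE]))
      obs_model <- suppressWarnings(
        estimate_msm(labels, mult * model$lag_frames))
      observed <- self_prob(obs_model, set)
      q1 <- q3 <- NA_real_
      if (!is.null(bootstrap)) {
        bs <- utils::modifyList(list(n_samples = 100, fraction = 0.95, seed = 1),
                                bootstrap)
        est <- function(trajs) {
          self_prob(suppressWarnings(
            estimate_msm(trajs, mult * model$lag_frames)), set)
        }
        b <- bootstrap_trajectories(est, labels, n_samples = bs$n_samples,
                                    fraction = bs$fraction, seed = bs$seed)
        q1 <- b$q1; q3 <- b$q3
      }
      rows[[length(rows) + 1L]] <- data.frame(
        set = si, multiple = mult, predicted = predicted,
        observed = observed, q1 = q1, q3 = q3)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ck_test", class(out))
  out
}

#' Trajectory bootstrap with quartile error bars
#'
#' Re-runs an estimator on repeated random subsets of the trajectories
#' (without replacement, all frames of a selected trajectory included) and
#' reports the first and third quartiles of the estimates as error bounds.
#' Defaults follow the error protocol of the receptor analyses: 500 samples
#' of 95% of the trajectories.
#'
#' @param estimator Function taking a list of trajectories and returning a
#'   numeric vector (its length must not depend on the subset).
#' @param trajectories List of trajectory objects (label vectors, feature
#'   matrices, ...).
#' @param n_samples Number of bootstrap samples (default 500).
#' @param fraction Fraction of trajectories per sample (default 0.95).
#' @param seed Integer seed.
#' @return Object of class `bootstrap_result`: `point` (estimator on all
#'   trajectories), `q1`, `q3`, `estimates` matrix, `n_failed`.
#' @export
bootstrap_trajectories <- function(estimator, trajectories, n_samples = 500,
                                   fraction = 0.95, seed = 1L) {
  n <- length(trajectories)
  if (n < 2) stopf("bootstrap needs at least 2 trajectories")
  m <- max(1L, round(fraction * n))
  point <- estimator(trajectories)
  p <- length(point)
  with_rng_seed(seed, {
    est <- matrix(NA_real_, n_samples, p)
    failed <- 0L
    for (b in seq_len(n_samples)) {
      idx <- sample.int(n, m)
      r <- tryCatch(suppressWarnings(estimator(trajectories[idx])),
                    error = function(e) NULL)
      if (is.null(r) || length(r) != p) failed <- failed + 1L
      else est[b, ] <- r
    }
    ok <- stats::complete.cases(est)
    if (!any(ok)) stopf("estimator failed on every bootstrap sample")
    q <- apply(est[ok, , drop = FALSE], 2, stats::quantile,
               probs = c(0.25, 0.75), na.rm = TRUE)
    structure(list(point = point, q1 = unname(q[1, ]), q3 = unname(q[2, ]),
                   estimates = est, n_failed = failed,
                   n_samples = n_samples, fraction = fraction),
              class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: %d samples (%.0f%% of trajectories), %d failed\n",
              x$n_samples, 100 * x$fraction, x$n_failed))
  for (i in seq_along(x$point)) {
    cat(sprintf("  [%d] %.6g  (Q1 %.6g, Q3 %.6g)\n", i, x$point[i],
                x$q1[i], x$q3[i]))
  }
  invisible(x)
}
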