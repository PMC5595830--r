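# PCCA+ metastable lumping and macrostate-level statistics: microstates are
# grouped by kinetic similarity using the simplex structure of the dominant
# right eigenvectors of the transition matrix.

#' Lump microstates into metastable macrostates (PCCA+)
#'
#' Takes the top `n_macrostates` right eigenvectors of a reversible
#' transition matrix, locates the vertices of the simplex their rows span
#' (inner simplex algorithm: iteratively pick the row farthest from the span
#' of the vertices found so far), and transforms eigenvector coordinates to
#' fuzzy memberships. Crisp assignment is by maximal membership. Macrostates
#' are renumbered by decreasing equilibrium probability, so labels are
#' reproducible across runs.
#'
#' @param model A `markov_model` (reversible).
#' @param n_macrostates Number of metastable states (the receptor analyses
#'   use 14).
#' @return Object of class `macrostate_model`: `assignment` (microstate ->
#'   macrostate, length = number of active microstates), `n_macrostates`,
#'   `macro_pi` (sums of microstate stationary probabilities),
#'   `memberships` (fuzzy), `active`, `lag_frames`.
#' @export
pcca_lump <- function(model, n_macrostates) {
  K <- model$n_states
  m <- n_macrostates
  if (!is_count(m) || m > K) stopf("n_macrostates must be in 1..%d", K)
  lambda <- model$lambda
  if (m < K && abs(lambda[m] - lambda[m + 1]) < 1e-12) {
    stopf("degenerate eigenvalues at the spectral cut (lambda_%d = lambda_%d); choose a different number of macrostates", m, m + 1)
  }
  if (sum(lambda > 0) < m) {
    stopf("only %d eigenvalues with positive real part; reduce n_macrostates",
          sum(lambda > 0))
  }
  if (m == 1L) {
    chi <- matrix(1, K, 1)
    assign <- rep(1L, K)
  } else {
    X <- model$psi[, seq_len(m), drop = FALSE]
    X[, 1] <- 1  # constant eigenvector, exactly
    ind <- integer(m)
    # vertex 1: row farthest from the origin
    ind[1] <- which.max(rowSums(X^2))
    Y <- sweep(X, 2, X[ind[1], ])
    for (j in 2:m) {
      d <- rowSums(Y^2)
      ind[j] <- which.max(d)
      if (d[ind[j]] < 1e-12) {
        stopf("eigenvector rows are affinely degenerate; reduce n_macrostates")
      }
      v <- Y[ind[j], ] / sqrt(d[ind[j]])
      Y <- Y - (Y %*% v) %*% t(v)
    }
    A <- solve(X[ind, , drop = FALSE])
    chi <- X %*% A
    assign <- max.col(chi, ties.method = "first")
  }
  if (length(unique(assign)) < m) {
    stopf("PCCA+ produced an empty macrostate; reduce n_macrostates")
  }
  macro_pi <- vapply(seq_len(m), function(M) sum(model$pi[assign == M]),
                     numeric(1))
  # canonical order: decreasing equilibrium probability
  ord <- order(-macro_pi)
  relabel <- integer(m); relabel[ord] <- seq_len(m)
  assign <- relabel[assign]
  chi <- chi[, ord, drop = FALSE]
  macro_pi <- macro_pi[ord]
  structure(list(assignment = assign, n_macrostates = m,
                 macro_pi = macro_pi, memberships = chi,
                 active = model$active, lag_frames = model$lag_frames),
            class = "macrostate_model")
}

#' @export
print.macrostate_model <- function(x, ...) {
  cat(sprintf("macrostate_model: %d macrostates over %d microstates\n",
              x$n_macrostates, length(x$assignment)))
  cat("equilibrium probabilities:",
      paste(sprintf("%.3g", x$macro_pi), collapse = " "), "\n")
  if (!is.null(x$regions)) {
    cat("regions:", paste(x$regions, collapse = ", "), "\n")
  }
  invisible(x)
}

# Microstates (original labels) belonging to macrostate M.
macro_members <- function(macro, M) macro$active[macro$assignment == M]

# Weighted quantile (inverse empirical CDF).
weighted_quantile <- function(v, w, probs) {
  o <- order(v)
  v <- v[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) v[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Per-macrostate statistics of order parameters
#'
#' Combines microstate trace averages with stationary-probability weights:
#' the macrostate mean of an order parameter is the pi-weighted average of
#' its microstate means, and the quartiles come from the pi-reweighted frame
#' distribution (each frame of microstate i carries weight pi_i / n_i).
#'
#' @param macro A `macrostate_model`.
#' @param model The `markov_model` it was derived from.
#' @param traces A single `op_trace` or named list of `op_trace`s,
#'   frame-aligned with `assignment`.
#' @param assignment The `microstate_assignment` used for the model.
#' @return Data frame: macrostate, trace, mean, q1, q3.
#' @export
macrostate_statistics <- function(macro, model, traces, assignment) {
  if (inherits(traces, "op_trace")) {
    traces <- stats::setNames(list(traces), traces$name)
  }
  labels <- assignment_labels(assignment)
  rows <- list()
  for (tn in names(traces)) {
    tr <- traces[[tn]]
    v <- unlist(tr$values)
    lab <- unlist(labels)
    if (length(v) != length(lab)) {
      stopf("trace '%s' is not frame-aligned with the assignment", tn)
    }
    keep <- lab %in% model$active
    v <- v[keep]; lab <- lab[keep]
    micro_idx <- match(lab, model$active)
    nframes <- tabulate(micro_idx, model$n_states)
    w <- model$pi[micro_idx] / nframes[micro_idx]
    for (M in seq_len(macro$n_macrostates)) {
      inM <- macro$assignment[micro_idx] == M
      if (!any(inM)) stopf("macrostate %d has no frames for trace '%s'", M, tn)
      q <- weighted_quantile(v[inM], w[inM], c(0.25, 0.75))
      rows[[length(rows) + 1L]] <- data.frame(
        macrostate = M, trace = tn,
        mean = sum(w[inM] * v[inM]) / sum(w[inM]),
        q1 = q[1], q3 = q[2], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

REGION_LEVELS <- c("inactive", "active", "intermediate_I", "intermediate_II")

#' Classify macrostates into activation regions
#'
#' Applies the activation-landscape grid on two per-macrostate averages: the
#' TM3-TM6 C-alpha distance and the NPxxY-segment RMSD from the inactive
#' reference. A macrostate is `inactive` when distance <= `dist_inactive`
#' and RMSD <= `rmsd_threshold` (boundaries inclusive); `intermediate_I`
#' when distance > `dist_active` with inactive-like RMSD; `active` when both
#' exceed their thresholds beyond `dist_active`; `intermediate_II` when the
#' RMSD is active-like but the distance lies between `dist_inactive` and
#' `dist_active`. Averages falling in the remaining cell (intermediate
#' distance, inactive-like RMSD) are returned as `NA` with a warning, since
#' the landscape's high-density regions do not populate it.
#'
#' @param stats Data frame with per-macrostate columns `tm6_distance` (A)
#'   and `npxxy_rmsd` (A).
#' @param dist_inactive Inactive-region distance bound (default 10 A).
#' @param rmsd_threshold NPxxY RMSD bound (default 2.5 A).
#' @param dist_active Upper distance bound separating the intermediate-II
#'   column from fully outward TM6 (default 13 A).
#' @return Character vector of region labels per row of `stats`.
#' @export
classify_region <- function(stats, dist_inactive = 10, rmsd_threshold = 2.5,
                            dist_active = 13) {
  if (!all(c("tm6_distance", "npxxy_rmsd") %in% names(stats))) {
    stopf("stats needs columns 'tm6_distance' and 'npxxy_rmsd'")
  }
  d <- stats$tm6_distance; r <- stats$npxxy_rmsd
  if (any(!is.finite(d)) || any(!is.finite(r))) stopf("missing statistic")
  out <- rep(NA_character_, length(d))
  out[d <= dist_inactive & r <= rmsd_threshold] <- "inactive"
  out[d > dist_active & r <= rmsd_threshold] <- "intermediate_I"
  out[d > dist_active & r > rmsd_threshold] <- "active"
  out[d > dist_inactive & d <= dist_active & r > rmsd_threshold] <- "intermediate_II"
  if (any(is.na(out))) {
    warnf("%d macrostate(s) fall in the unclassified cell (%.3g < distance <= %.3g, RMSD <= %.3g)",
          sum(is.na(out)), dist_inactive, dist_active, rmsd_threshold)
  }
  out
}

#' Kinetic evolution of macrostate occupancies
#'
#' Starting from a probability vector proportional to the equilibrium
#' microstate probabilities inside the source macrostate(s) (zero
#' elsewhere), propagates `p(t) = p0 T^t` on microstates and projects onto
#' macrostates after every application of the transition matrix.
#'
#' @param model A `markov_model`.
#' @param macro A `macrostate_model` from the same model.
#' @param source Macrostate index (or vector of indices) to start from, or
#'   a region label when `macro$regions` is set.
#' @param horizon Number of lag steps to propagate.
#' @return Data frame: `step`, `time_frames`, one occupancy column per
#'   macrostate (`macro_1`, ...). Rows sum to 1 across macrostates.
#' @export
kinetic_evolution <- function(model, macro, source, horizon) {
  if (!is_count(horizon)) stopf("horizon must be a positive integer")
  if (is.character(source)) {
    if (is.null(macro$regions)) stopf("macro has no region labels; pass macrostate indices")
    source <- which(macro$regions %in% source)
  }
  if (length(source) == 0L) stopf("empty source set")
  micro <- which(macro$assignment %in% source)
  p <- numeric(model$n_states)
  p[micro] <- model$pi[micro]
  p <- p / sum(p)
  occ <- matrix(0, horizon + 1L, macro$n_macrostates)
  project <- function(p) {
    vapply(seq_len(macro$n_macrostates),
           function(M) sum(p[macro$assignment == M]), numeric(1))
  }
  occ[1, ] <- project(p)
  for (t in seq_len(horizon)) {
    p <- as.numeric(p %*% model$T)
    occ[t + 1L, ] <- project(p)
  }
  out <- data.frame(step = 0:horizon,
                    time_frames = (0:horizon) * model$lag_frames)
  occ <- as.data.frame(occ)
  names(occ) <- sprintf("macro_%d", seq_len(macro$n_macrostates))
  cbind(out, occ)
}

#' Representative microstate frames for a macrostate
#'
#' Utility: indices of the frames closest to each member microstate's
#' cluster center, useful for extracting representative conformations.
#'
#' @param macro A `macrostate_model`.
#' @param assignment A `microstate_assignment` (with centers).
#' @param projections The projections used for clustering.
#' @param M Macrostate index.
#' @return Data frame: microstate, trajectory, frame.
#' @export
representative_frames <- function(macro, assignment, projections, M) {
  ps <- if (is.matrix(projections)) list(projections) else projections
  members <- macro_members(macro, M)
  rows <- list()
  for (mu in members) {
    best <- c(Inf, NA, NA)
    for (tr in seq_along(ps)) {
      sel <- which(assignment$labels[[tr]] == mu)
      if (length(sel) == 0L) next
      d2 <- rowSums(sweep(ps[[tr]][sel, , drop = FALSE], 2,
                          assignment$centers[mu, ])^2)
      i <- which.min(d2)
      if (d2[i] < best[1]) best <- c(d2[i], tr, sel[i])
    }
    if (!is.na(best[2])) {
      rows[[length(rows) + 1L]] <- data.frame(
        microstate = mu, trajectory = best[2], frame = best[3])
    }
  }
  do.call(rbind, rows)
}
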