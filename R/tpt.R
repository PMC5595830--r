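# Transition path theory between two sets of microstates: forward
# committors, reactive flux networks, flux-ranked pathway decomposition and
# mean first-passage times.

check_sets <- function(model, A, B) {
  if (length(A) == 0L || length(B) == 0L) stopf("A and B must be non-empty")
  if (length(intersect(A, B))) stopf("A and B must be disjoint")
  if (!all(c(A, B) %in% model$active)) stopf("A and B must lie in the active set")
}

#' Forward committor between two microstate sets
#'
#' Probability, for every microstate, of reaching set `B` before set `A`.
#' Solves the committor linear system on the intermediate states with
#' boundary conditions q = 0 on A, q = 1 on B.
#'
#' @param model A `markov_model`.
#' @param A,B Disjoint sets of microstate labels (original labels, within
#'   the active set).
#' @return Object of class `committor_field`: `q` (named by microstate
#'   label), `A`, `B`.
#' @export
committor <- function(model, A, B) {
  check_sets(model, A, B)
  states <- model$active
  ia <- match(A, states); ib <- match(B, states)
  inter <- setdiff(seq_along(states), c(ia, ib))
  q <- numeric(length(states))
  q[ib] <- 1
  if (length(inter) > 0) {
    Tm <- model$T
    M <- diag(length(inter)) - Tm[inter, inter, drop = FALSE]
    rhs <- rowSums(Tm[inter, ib, drop = FALSE])
    sol <- tryCatch(solve(M, rhs), error = function(e) {
      stopf("committor system is singular (disconnected intermediate states)")
    })
    q[inter] <- sol
  }
  q <- pmin(1, pmax(0, q))
  structure(list(q = stats::setNames(q, states), A = A, B = B),
            class = "committor_field")
}

#' @export
print.committor_field <- function(x, ...) {
  cat(sprintf("committor_field: |A| = %d, |B| = %d, %d states\n",
              length(x$A), length(x$B), length(x$q)))
  invisible(x)
}

#' Reactive flux network between two sets
#'
#' Gross reactive flux `f_ij = pi_i (1 - q_i) T_ij q_j` for i != j, net flux
#' `max(f_ij - f_ji, 0)`, and the total A->B flux. Optionally coarse-grains
#' the network over a macrostate map by summing gross fluxes over macrostate
#' pairs before taking the net.
#'
#' @param model A `markov_model`.
#' @param com A `committor_field` from the same model.
#' @param macro Optional `macrostate_model` for coarse-graining.
#' @return Object of class `flux_network`: `net` (microstate-level net flux
#'   matrix), `gross`, `total_flux`, and when `macro` is given
#'   `macro_net`, `macro_gross`, `macro_of` (macrostate of each microstate).
#' @export
reactive_flux <- function(model, com, macro = NULL) {
  states <- model$active
  q <- com$q[as.character(states)]
  qm <- 1 - q
  f <- (model$pi * qm) * model$T * matrix(q, length(q), length(q), byrow = TRUE)
  diag(f) <- 0
  net <- pmax(f - t(f), 0)
  ia <- match(com$A, states)
  total <- sum(f[ia, , drop = FALSE]) - sum(f[, ia, drop = FALSE])
  out <- list(net = net, gross = f, total_flux = total, states = states,
              A = com$A, B = com$B)
  if (!is.null(macro)) {
    m <- macro$n_macrostates
    agg <- matrix(0, m, m)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i == j) next
        agg[i, j] <- sum(f[macro$assignment == i, macro$assignment == j])
      }
    }
    out$macro_gross <- agg
    out$macro_net <- pmax(agg - t(agg), 0)
    out$macro_of <- macro$assignment
    out$macro_A <- unique(macro$assignment[match(com$A, states)])
    out$macro_B <- unique(macro$assignment[match(com$B, states)])
  }
  class(out) <- "flux_network"
  out
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("flux_network: total A->B flux %.6g per lag step\n", x$total_flux))
  invisible(x)
}

# Widest (maximum-bottleneck) path from any source to any sink on a
# non-negative flux matrix; Dijkstra-style with max-min relaxation.
widest_path <- function(F, sources, sinks) {
  n <- nrow(F)
  width <- rep(-Inf, n); width[sources] <- Inf
  prev <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  repeat {
    u <- which(!visited & width > -Inf)
    if (length(u) == 0L) break
    u <- u[which.max(width[u])]
    visited[u] <- TRUE
    if (u %in% sinks) {
      path <- u
      while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
      return(list(path = path, width = width[u]))
    }
    for (v in which(F[u, ] > 0 & !visited)) {
      w <- min(width[u], F[u, v])
      if (w > width[v]) { width[v] <- w; prev[v] <- u }
    }
  }
  NULL
}

#' Decompose a flux network into ranked pathways
#'
#' Iterative bottleneck-removal decomposition on the macrostate-level net
#' flux graph: repeatedly extract the widest A->B path, assign it the flux
#' of its bottleneck edge, subtract that flux along the path, and continue
#' until the residual flux is exhausted. Pathways carrying at least
#' `min_fraction` of the total flux are returned, ranked by flux.
#'
#' @param flux A `flux_network` computed with a macrostate map.
#' @param min_fraction Smallest reported flux fraction (default 0.01, i.e.
#'   pathways with more than 1% of the flux).
#' @return Object of class `pathway_decomposition`: data frame `pathways`
#'   (macrostate sequence, flux, fraction) plus `total_flux`.
#' @export
decompose_pathways <- function(flux, min_fraction = 0.01) {
  if (is.null(flux$macro_net)) stopf("flux network lacks a macrostate coarse-graining")
  Fnet <- flux$macro_net
  total <- sum(Fnet[flux$macro_A, , drop = FALSE]) -
    sum(Fnet[, flux$macro_A, drop = FALSE])
  if (total <= 0) stopf("total flux is zero; nothing to decompose")
  paths <- list()
  residual <- total
  guard <- 0L
  while (residual > 1e-12 * total) {
    guard <- guard + 1L
    if (guard > 10000L) stopf("pathway decomposition failed to terminate (cyclic residual flux)")
    wp <- widest_path(Fnet, flux$macro_A, flux$macro_B)
    if (is.null(wp)) {
      if (residual > 1e-6 * total) {
        stopf("residual flux %.3g cannot reach B (cyclic residual flux indicates an upstream error)",
              residual)
      }
      break
    }
    f <- wp$width
    for (e in seq_len(length(wp$path) - 1L)) {
      Fnet[wp$path[e], wp$path[e + 1L]] <-
        Fnet[wp$path[e], wp$path[e + 1L]] - f
    }
    paths[[length(paths) + 1L]] <- list(path = wp$path, flux = f)
    residual <- residual - f
  }
  df <- data.frame(
    pathway = vapply(paths, function(p) paste(p$path, collapse = " -> "),
                     character(1)),
    flux = vapply(paths, function(p) p$flux, numeric(1)))
  df$fraction <- df$flux / total
  df <- df[order(-df$flux), , drop = FALSE]
  df <- df[df$fraction >= min_fraction, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(pathways = df, total_flux = total),
            class = "pathway_decomposition")
}

#' @export
print.pathway_decomposition <- function(x, ...) {
  cat(sprintf("pathway_decomposition: total flux %.6g\n", x$total_flux))
  print(x$pathways)
  invisible(x)
}

#' Mean first-passage time between microstate sets
#'
#' Expected number of lag steps to first hit `target`, starting from
#' `source`, from the first-step linear system; the source value is the
#' average over source microstates weighted by the stationary distribution
#' restricted to the source. Physical time is steps x lag x frame interval.
#'
#' @param model A `markov_model`.
#' @param source,target Disjoint sets of microstate labels.
#' @return List of class `mfpt_result`: `steps`, `frames`, `ns` (when the
#'   model has a frame interval), `per_state` (hitting time per microstate).
#'   Unreachable targets give `Inf` with a flag.
#' @export
mfpt <- function(model, source, target) {
  if (length(intersect(source, target))) {
    if (all(source %in% target)) {
      return(structure(list(steps = 0, frames = 0,
                            ns = if (!is.null(model$frame_interval_ns)) 0 else NA_real_,
                            unreachable = FALSE),
                       class = "mfpt_result"))
    }
    stopf("source and target must be disjoint (or identical)")
  }
  check_sets(model, source, target)
  states <- model$active
  it <- match(target, states)
  rest <- setdiff(seq_along(states), it)
  Tm <- model$T
  M <- diag(length(rest)) - Tm[rest, rest, drop = FALSE]
  h <- rep(Inf, length(states))
  h[it] <- 0
  sol <- tryCatch(solve(M, rep(1, length(rest))), error = function(e) NULL)
  unreachable <- FALSE
  if (is.null(sol) || any(sol < 0) || any(!is.finite(sol))) {
    unreachable <- TRUE
  } else {
    h[rest] <- sol
  }
  is_ <- match(source, states)
  w <- model$pi[is_] / sum(model$pi[is_])
  steps <- sum(w * h[is_])
  frames <- steps * model$lag_frames
  ns <- if (!is.null(model$frame_interval_ns)) frames * model$frame_interval_ns
        else NA_real_
  structure(list(steps = steps, frames = frames, ns = ns,
                 per_state = stats::setNames(h, states),
                 unreachable = unreachable || !is.finite(steps)),
            class = "mfpt_result")
}

#' @export
print.mfpt_result <- function(x, ...) {
  cat(sprintf("mfpt: %.6g steps (%.6g frames%s)%s\n", x$steps, x$frames,
              if (!is.na(x$ns)) sprintf(", %.6g ns", x$ns) else "",
              if (x$unreachable) " [target unreachable]" else ""))
  invisible(x)
}

#' Macrostate-level MFPT matrix
#'
#' MFPTs between every ordered pair of macrostates, using each macrostate's
#' full microstate set as the target and pi-restricted averaging over the
#' source set.
#'
#' @param model A `markov_model`.
#' @param macro A `macrostate_model`.
#' @return Matrix (macrostates x macrostates) of MFPTs in lag steps;
#'   diagonal 0.
#' @export
mfpt_matrix <- function(model, macro) {
  m <- macro$n_macrostates
  out <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      out[i, j] <- mfpt(model, macro_members(macro, i),
                        macro_members(macro, j))$steps
    }
  }
  out
}

#' Export a macrostate flux network as a DOT graph
#'
#' @param flux A `flux_network` with macrostate coarse-graining.
#' @param path Output file.
#' @export
write_flux_dot <- function(flux, path) {
  if (is.null(flux$macro_net)) stopf("flux network lacks a macrostate coarse-graining")
  lines <- c("digraph flux {")
  Fn <- flux$macro_net
  for (i in seq_len(nrow(Fn))) {
    for (j in seq_len(ncol(Fn))) {
      if (Fn[i, j] > 0) {
        lines <- c(lines, sprintf("  m%d -> m%d [label=\"%.3g\"];", i, j, Fn[i, j]))
      }
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
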