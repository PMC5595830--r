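# Directed information flow between residues: shuffle-corrected transfer
# entropy on binary contact dynamics, directed-graph construction, HITS
# hub/authority scoring and transmitter/receiver/connector roles.

#' Group contact columns into per-node state series
#'
#' Each node (residue or ligand) is described by the vector of its binary
#' contacts in every frame; the vector is treated as one discrete symbol, so
#' a node with c contact columns has an alphabet of at most 2^c symbols. A
#' residue-residue contact column may feed both residues' vectors.
#'
#' @param contacts A `feature_set` whose referenced columns are binary, or a
#'   list of binary matrices.
#' @param grouping Named list: node name -> column names or indices.
#' @return Object of class `contact_trace`: `symbols` (per node: list of
#'   integer symbol vectors, one per trajectory), `alphabet` (per-node count
#'   of distinct observed symbols), `nodes`.
#' @export
residue_state_series <- function(contacts, grouping) {
  xs <- feature_matrices(contacts)
  if (length(grouping) == 0L) stopf("grouping is empty")
  nodes <- names(grouping)
  if (is.null(nodes) || any(nodes == "")) stopf("grouping must be a named list")
  symbols <- vector("list", length(nodes))
  names(symbols) <- nodes
  alphabet <- integer(length(nodes))
  names(alphabet) <- nodes
  for (nd in nodes) {
    cols <- grouping[[nd]]
    per_traj <- lapply(xs, function(x) {
      sub <- x[, cols, drop = FALSE]
      if (!all(sub %in% c(0, 1))) stopf("node '%s' references non-binary columns", nd)
      # pack the contact vector into one integer symbol
      as.integer(sub %*% 2^(seq_len(ncol(sub)) - 1L))
    })
    symbols[[nd]] <- per_traj
    alphabet[nd] <- length(unique(unlist(per_traj)))
  }
  structure(list(symbols = symbols, alphabet = alphabet, nodes = nodes),
            class = "contact_trace")
}

#' @export
print.contact_trace <- function(x, ...) {
  cat(sprintf("contact_trace: %d nodes, %d trajectories, alphabet sizes %s\n",
              length(x$nodes), length(x$symbols[[1]]),
              paste(utils::head(x$alphabet, 8), collapse = ",")))
  invisible(x)
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

as_symbol_list <- function(x) {
  if (is.list(x)) lapply(x, as.integer) else list(as.integer(x))
}

# Pooled (target_next, target_now, source_now) triples across trajectories.
te_triples <- function(xs, ys, lag) {
  inext <- integer(0); inow <- integer(0); jnow <- integer(0)
  for (k in seq_along(xs)) {
    x <- xs[[k]]; y <- ys[[k]]
    n <- length(y)
    if (length(x) != n) stopf("source and target trajectories are not frame-aligned")
    if (n <= lag) stopf("trajectory of %d frames is not longer than the lag (%d)", n, lag)
    inext <- c(inext, y[(1 + lag):n])
    inow <- c(inow, y[1:(n - lag)])
    jnow <- c(jnow, x[1:(n - lag)])
  }
  a <- match(inext, sort(unique(inext)))
  b <- match(inow, sort(unique(inow)))
  cc <- match(jnow, sort(unique(jnow)))
  list(a = a, b = b, c = cc,
       Ka = max(a), Kb = max(b), Kc = max(cc))
}

te_from_triples <- function(tr, method) {
  a <- tr$a; b <- tr$b; cc <- tr$c
  Ka <- tr$Ka; Kb <- tr$Kb; Kc <- tr$Kc
  n_ab <- tabulate((a - 1L) * Kb + b, Ka * Kb)
  n_b <- tabulate(b, Kb)
  n_bc <- tabulate((b - 1L) * Kc + cc, Kb * Kc)
  n_abc <- tabulate(((a - 1L) * Kb + (b - 1L)) * Kc + cc, Ka * Kb * Kc)
  if (method == "entropy") {
    return(entropy_bits(n_ab) - entropy_bits(n_b) -
             entropy_bits(n_abc) + entropy_bits(n_bc))
  }
  # direct summation of the transfer-entropy definition over the empirical
  # joint distribution
  N <- length(a)
  iabc <- ((a - 1L) * Kb + (b - 1L)) * Kc + cc
  iab <- (a - 1L) * Kb + b
  ibc <- (b - 1L) * Kc + cc
  cnt <- n_abc[iabc]
  ratio <- (cnt * n_b[b]) / (n_bc[ibc] * n_ab[iab])
  sum(log2(ratio)) / N
}

#' Transfer entropy between two symbol series
#'
#' Plug-in estimate (log base 2, bits) of the transfer entropy from a source
#' to a target series at a given lag: the reduction in uncertainty of the
#' target's next symbol given the source's current symbol, beyond the
#' target's own history. The finite-sample bias is corrected by subtracting
#' the same estimate computed after randomly permuting the source's time
#' indices (within each trajectory).
#'
#' @param source,target Integer/binary vectors, or lists of vectors (one per
#'   trajectory), frame-aligned.
#' @param lag Lag in frames (>= 1).
#' @param shuffle Apply the shuffle correction (default TRUE).
#' @param n_permutations Number of permutations averaged for the baseline.
#' @param seed Seed for the permutations.
#' @param method `"entropy"` (default; four-term entropy decomposition) or
#'   `"direct"` (direct summation over the empirical joint distribution);
#'   the two are algebraically identical.
#' @return List: `te` (corrected, bits), `raw`, `baseline`.
#' @export
transfer_entropy <- function(source, target, lag = 1L, shuffle = TRUE,
                             n_permutations = 1L, seed = 1L,
                             method = c("entropy", "direct")) {
  method <- match.arg(method)
  if (!is_count(lag)) stopf("lag must be a positive integer")
  xs <- as_symbol_list(source)
  ys <- as_symbol_list(target)
  if (length(xs) != length(ys)) stopf("source and target must have the same trajectory count")
  raw <- te_from_triples(te_triples(xs, ys, lag), method)
  baseline <- 0
  if (shuffle) {
    baseline <- with_rng_seed(seed, {
      vals <- numeric(n_permutations)
      for (p in seq_len(n_permutations)) {
        xp <- lapply(xs, function(x) x[sample.int(length(x))])
        vals[p] <- te_from_triples(te_triples(xp, ys, lag), method)
      }
      mean(vals)
    })
  }
  list(te = raw - baseline, raw = raw, baseline = baseline)
}

#' Pairwise transfer-entropy matrix over a contact trace
#'
#' For each of `n_repeats` runs, draws a random subset of the trajectories
#' (without replacement), computes the shuffle-corrected transfer entropy
#' for every ordered node pair, and averages the runs. Defaults follow the
#' receptor protocol: 30% of the trajectories, 3 repeats.
#'
#' @param traces A `contact_trace`.
#' @param lag Lag in frames.
#' @param subsample_fraction Fraction of trajectories per run (default 0.3).
#' @param n_repeats Number of independent runs averaged (default 3).
#' @param seed Integer seed (run r uses seed + r - 1).
#' @return Object of class `te_matrix`: `te` (N x N, entry [i, j] = corrected
#'   transfer entropy from node i to node j, bits, diagonal 0), `raw`,
#'   `baseline`, metadata.
#' @export
te_matrix <- function(traces, lag = 1L, subsample_fraction = 0.3,
                      n_repeats = 3L, seed = 1L) {
  nodes <- traces$nodes
  N <- length(nodes)
  ntraj <- length(traces$symbols[[1]])
  m <- max(1L, round(subsample_fraction * ntraj))
  acc <- matrix(0, N, N, dimnames = list(nodes, nodes))
  acc_raw <- acc; acc_base <- acc
  for (r in seq_len(n_repeats)) {
    idx <- sort(with_rng_seed(seed + r - 1L, sample.int(ntraj, m)))
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        if (i == j) next
        res <- transfer_entropy(traces$symbols[[i]][idx],
                                traces$symbols[[j]][idx],
                                lag = lag, seed = seed + r - 1L)
        acc[i, j] <- acc[i, j] + res$te
        acc_raw[i, j] <- acc_raw[i, j] + res$raw
        acc_base[i, j] <- acc_base[i, j] + res$baseline
      }
    }
  }
  structure(list(te = acc / n_repeats, raw = acc_raw / n_repeats,
                 baseline = acc_base / n_repeats, lag = lag,
                 subsample_fraction = subsample_fraction,
                 n_repeats = n_repeats, seed = seed, nodes = nodes),
            class = "te_matrix")
}

#' @export
print.te_matrix <- function(x, ...) {
  cat(sprintf("te_matrix: %d nodes, lag %d, %d repeats at %.0f%% of trajectories\n",
              length(x$nodes), x$lag, x$n_repeats,
              100 * x$subsample_fraction))
  cat(sprintf("max corrected TE: %.4g bits\n", max(x$te)))
  invisible(x)
}

#' HITS hub and authority scores on a transfer-entropy graph
#'
#' Builds the weighted directed graph whose edge u -> v carries the
#' corrected transfer entropy from u to v (negative values clipped to 0)
#' and runs HITS power iteration to convergence 1e-12. Authority scores
#' rank nodes as receivers of information, hub scores as transmitters;
#' both are normalized so the maximum is 1.
#'
#' @param tem A `te_matrix`, or a non-negative weighted adjacency matrix.
#' @return Object of class `node_scores`: data frame `scores` (node,
#'   authority, hub).
#' @export
hits_scores <- function(tem) {
  A <- if (inherits(tem, "te_matrix")) pmax(tem$te, 0) else as.matrix(tem)
  if (any(A < 0)) stopf("adjacency weights must be non-negative")
  diag(A) <- 0
  if (all(A == 0)) stopf("all edge weights are zero after clipping")
  n <- nrow(A)
  h <- rep(1 / sqrt(n), n)
  a <- rep(1 / sqrt(n), n)
  for (it in seq_len(100000L)) {
    a_new <- as.numeric(crossprod(A, h))
    a_new <- a_new / sqrt(sum(a_new^2))
    h_new <- as.numeric(A %*% a_new)
    h_new <- h_new / sqrt(sum(h_new^2))
    if (max(abs(a_new - a)) < 1e-12 && max(abs(h_new - h)) < 1e-12) {
      a <- a_new; h <- h_new
      break
    }
    a <- a_new; h <- h_new
  }
  nodes <- rownames(A)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  structure(list(scores = data.frame(node = nodes,
                                     authority = a / max(a),
                                     hub = h / max(h),
                                     stringsAsFactors = FALSE)),
            class = "node_scores")
}

#' @export
print.node_scores <- function(x, ...) {
  cat("node_scores:\n")
  print(x$scores, row.names = FALSE)
  invisible(x)
}

#' Classify nodes into information-flow roles
#'
#' A node is a transmitter when only its hub score passes its threshold, a
#' receiver when only its authority score does, and a connector when both
#' do (good at both receiving and transmitting information).
#'
#' @param scores A `node_scores`.
#' @param hub_threshold,authority_threshold Thresholds on the
#'   max-normalized scores, in (0, 1] (default 0.5).
#' @return Data frame: node, authority, hub, role (transmitter / receiver /
#'   connector / none).
#' @export
classify_roles <- function(scores, hub_threshold = 0.5,
                           authority_threshold = 0.5) {
  if (hub_threshold <= 0 || hub_threshold > 1 ||
      authority_threshold <= 0 || authority_threshold > 1) {
    stopf("thresholds must lie in (0, 1]")
  }
  s <- scores$scores
  hi_h <- s$hub >= hub_threshold
  hi_a <- s$authority >= authority_threshold
  s$role <- ifelse(hi_h & hi_a, "connector",
            ifelse(hi_h, "transmitter",
            ifelse(hi_a, "receiver", "none")))
  s
}

#' Write a transfer-entropy graph as an edge list
#'
#' @param tem A `te_matrix`.
#' @param path Output CSV path (columns: from, to, te_bits).
#' @param min_te Smallest edge written (default > 0).
#' @export
write_te_edgelist <- function(tem, path, min_te = 0) {
  A <- pmax(tem$te, 0)
  idx <- which(A > min_te, arr.ind = TRUE)
  df <- data.frame(from = tem$nodes[idx[, 1]], to = tem$nodes[idx[, 2]],
                   te_bits = A[idx])
  utils::write.csv(df[order(-df$te_bits), ], path, row.names = FALSE)
  invisible(path)
}
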