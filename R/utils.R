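# Shared internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package funnel through this so results are reproducible per call without
# clobbering the session RNG.
with_rng_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

check_prob_matrix <- function(P, tol = 1e-12) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stopf("transition matrix must be square")
  }
  if (any(!is.finite(P)) || any(P < 0)) {
    stopf("transition matrix entries must be finite and non-negative")
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > tol)) {
    stopf("transition matrix rows must sum to 1 (max deviation %.3g)",
          max(abs(rs - 1)))
  }
  invisible(P)
}

# Euclidean distance between two coordinate rows.
vec_dist <- function(a, b) sqrt(sum((a - b)^2))

# Row-wise euclidean norm of an n x 3 displacement.
row_norms <- function(m) sqrt(rowSums(m * m))

# Minimum pairwise distance between two coordinate sets (n x 3, m x 3).
min_cross_dist <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}
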