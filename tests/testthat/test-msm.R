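test_that("reversible MLE reproduces the closed form for 2-state counts", {
  C <- matrix(c(90, 10, 20, 80), 2, byrow = TRUE)
  fit <- kinflow:::reversible_mle(C)
  expect_equal(fit$T, matrix(c(.9, .1, .2, .8), 2, byrow = TRUE),
               tolerance = 1e-9)
  expect_equal(fit$pi, c(2 / 3, 1 / 3), tolerance = 1e-9)
})

test_that("reversible estimate is a local likelihood optimum", {
  C <- matrix(c(50, 6, 3, 10, 70, 4, 2, 8, 60), 3, byrow = TRUE)
  fit <- kinflow:::reversible_mle(C)
  loglik <- function(T) sum(C[T > 0] * log(T[T > 0]))
  base <- loglik(fit$T)
  set.seed(1)
  for (rep in 1:20) {
    # reversibility-preserving perturbation of the symmetric flows
    X <- fit$pi * fit$T
    eps <- matrix(rnorm(9, sd = 1e-4), 3); eps <- eps + t(eps)
    Xp <- pmax(X * (1 + eps), 1e-12); Xp <- (Xp + t(Xp)) / 2
    Tp <- Xp / rowSums(Xp)
    expect_lte(loglik(Tp), base + 1e-12)
  }
})

test_that("estimated models satisfy detailed balance and recover the chain", {
  P <- matrix(c(.9, .1, .2, .8), 2, byrow = TRUE)
  trajs <- lapply(1:10, function(i) simulate_markov_chain(P, 20000, seed = i))
  m <- estimate_msm(trajs, lag = 1)
  expect_lt(max(abs(m$pi - c(2 / 3, 1 / 3))), 0.02)
  expect_lt(max(abs(m$T - P)), 0.02)
  flow <- m$pi * m$T
  expect_lt(max(abs(flow - t(flow))), 1e-10)
  expect_equal(rowSums(m$T), rep(1, 2), tolerance = 1e-10)
})

test_that("disconnected blocks are trimmed to the largest ergodic set", {
  # two disconnected 2-state blocks; block {1,2} has three times the frames
  t1 <- rep(c(1L, 2L), 300)
  t2 <- rep(c(3L, 4L), 100)
  expect_warning(m <- estimate_msm(list(t1, t2), lag = 1), "strongly connected")
  expect_equal(m$active, c(1L, 2L))
  expect_error(estimate_msm(list(c(1L, 1L)), lag = 5), "no transitions")
})

test_that("implied timescales follow the eigenvalue formula and are flat", {
  # symmetric switch chain: lambda_2 = 1 - 2p = 0.7 -> t2 = -1/ln(0.7)
  P <- matrix(c(.85, .15, .15, .85), 2, byrow = TRUE)
  trajs <- lapply(1:10, function(i) simulate_markov_chain(P, 30000, seed = 10 + i))
  its <- implied_timescales(trajs, lags = c(1L, 2L, 5L), n_timescales = 1,
                            bootstrap = list(n_samples = 50, seed = 1))
  exact <- -1 / log(0.7)
  expect_equal(its$timescale_frames[its$lag_frames == 1], exact,
               tolerance = 0.05)
  # Markovian data: curves flat across lags within overlapping quartile bands
  for (i in seq_len(nrow(its))) {
    for (j in seq_len(nrow(its))) {
      expect_lt(its$q1_frames[i], its$q3_frames[j] + 0.05 * exact)
    }
  }
  # physical units scale by the frame interval
  its_ns <- implied_timescales(trajs, lags = 1L, n_timescales = 1,
                               frame_interval_ns = 0.1)
  expect_equal(its_ns$timescale_ns, its_ns$timescale_frames * 0.1)
  # timescales invariant to trajectory ordering
  its_rev <- implied_timescales(rev(trajs), lags = c(1L, 2L, 5L),
                                n_timescales = 1)
  expect_equal(its_rev$timescale_frames,
               implied_timescales(trajs, lags = c(1L, 2L, 5L),
                                  n_timescales = 1)$timescale_frames)
})

test_that("near-unit eigenvalues are flagged as infinite timescales", {
  ts <- kinflow:::implied_ts_from_lambda(c(1, 1 - 1e-14, 0.5), lag = 1)
  expect_true(is.infinite(ts[2]))
  expect_equal(ts[3], -1 / log(0.5))
})

test_that("Chapman-Kolmogorov test validates Markovian data and flags lumping", {
  P <- matrix(c(.9, .1, .2, .8), 2, byrow = TRUE)
  trajs <- lapply(1:8, function(i) simulate_markov_chain(P, 20000, seed = 30 + i))
  m <- estimate_msm(trajs, lag = 1)
  ck <- ck_test(m, trajs, sets = list(1L, 2L), multiples = 1:4)
  m1 <- ck[ck$multiple == 1, ]
  expect_equal(m1$predicted, m1$observed, tolerance = 1e-12)
  expect_lt(max(abs(ck$predicted - ck$observed)), 0.02)
  # deterministic period-3 cycle, lumped {1,2}->1, {3}->2: strongly
  # non-Markovian observation, CK must show a visible violation
  lump <- rep(c(1L, 1L, 2L), 400)
  ml <- estimate_msm(list(lump), lag = 1)
  ckl <- ck_test(ml, list(lump), sets = list(1L), multiples = c(1L, 2L))
  v <- ckl[ckl$multiple == 2, ]
  expect_gt(abs(v$predicted - v$observed), 0.2)
  expect_error(ck_test(m, trajs, sets = list(1L, 1:2), multiples = 1),
               "disjoint")
})

test_that("markov models can be built from an explicit transition matrix", {
  P <- chain3()
  m <- as_markov_model(P, lag_frames = 2L, frame_interval_ns = 0.5)
  expect_equal(m$T, P)
  expect_equal(as.numeric(m$pi %*% P), m$pi, tolerance = 1e-12)
  expect_equal(m$lambda[1], 1, tolerance = 1e-12)
  expect_warning(as_markov_model(matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3,
                                        byrow = TRUE)), "reversible")
})

test_that("trajectory bootstrap reports quartiles and tolerates failures", {
  b <- bootstrap_trajectories(function(x) 5, as.list(1:10),
                              n_samples = 40, seed = 1)
  expect_equal(b$q1, 5); expect_equal(b$q3, 5); expect_equal(b$n_failed, 0L)
  # estimator failing on subsets missing trajectory 1 is recorded, excluded
  flaky <- function(x) {
    if (!(1 %in% unlist(x))) stop("need trajectory 1")
    mean(unlist(x))
  }
  b2 <- bootstrap_trajectories(flaky, as.list(1:5), n_samples = 60,
                               fraction = 0.6, seed = 2)
  expect_gt(b2$n_failed, 0)
  expect_true(b2$q1 <= b2$q3)
  expect_error(bootstrap_trajectories(function(x) 1, list(1)), "at least 2")
  # deterministic per seed
  est <- function(x) mean(unlist(x))
  b3 <- bootstrap_trajectories(est, as.list(1:10), n_samples = 20, seed = 5)
  b4 <- bootstrap_trajectories(est, as.list(1:10), n_samples = 20, seed = 5)
  expect_identical(b3$estimates, b4$estimates)
})
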