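test_that("contact columns group into per-node symbol alphabets", {
  set.seed(1)
  x <- matrix(rbinom(300, 1, 0.5), ncol = 3)
  colnames(x) <- c("c1", "c2", "c3")
  tr <- residue_state_series(list(x), list(a = "c1", b = c("c1", "c2", "c3")))
  expect_lte(tr$alphabet[["a"]], 2L)
  expect_equal(tr$alphabet[["b"]], 8L)  # all combinations observed at n=100
  xc <- cbind(k = rep(1, 50))
  trc <- residue_state_series(list(xc), list(k = "k"))
  expect_equal(trc$alphabet[["k"]], 1L)
  bad <- cbind(v = rnorm(10))
  expect_error(residue_state_series(list(bad), list(v = "v")), "non-binary")
})

test_that("transfer entropy identifies the planted coupling direction", {
  x <- simulate_coupled_contacts(2, data.frame(driver = 1, follower = 2),
                                 lag = 1, noise_prob = 0, n_frames = 100000,
                                 seed = 3)
  fwd <- transfer_entropy(x[, 1], x[, 2], lag = 1, seed = 9)
  rev <- transfer_entropy(x[, 2], x[, 1], lag = 1, seed = 9)
  expect_equal(fwd$te, 1, tolerance = 0.02)
  expect_lt(abs(rev$te), 0.01)
  # maximal noise destroys the coupling in both directions
  xn <- simulate_coupled_contacts(2, data.frame(driver = 1, follower = 2),
                                  lag = 1, noise_prob = 0.5,
                                  n_frames = 100000, seed = 6)
  expect_lt(abs(transfer_entropy(xn[, 1], xn[, 2], seed = 2)$te), 0.01)
  expect_lt(abs(transfer_entropy(xn[, 2], xn[, 1], seed = 2)$te), 0.01)
})

test_that("corrected TE concentrates near zero for independent processes", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- rbinom(100000, 1, 0.5); b <- rbinom(100000, 1, 0.5)
    expect_lt(abs(transfer_entropy(a, b, seed = 100 + seed)$te), 0.01)
  }
})

test_that("direct summation equals the entropy decomposition exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 400
    a <- rbinom(n, 1, runif(1, 0.2, 0.8))
    b <- as.integer(bitwXor(c(0L, a[-n]), rbinom(n, 1, 0.3)))
    d <- transfer_entropy(a, b, shuffle = FALSE, method = "direct")$raw
    e <- transfer_entropy(a, b, shuffle = FALSE, method = "entropy")$raw
    expect_equal(d, e, tolerance = 1e-12)
    expect_gte(e, -1e-12)  # plug-in TE is non-negative before correction
  }
})

test_that("TE matrix averages subsampled runs and stays deterministic", {
  contacts <- lapply(1:10, function(i) {
    simulate_coupled_contacts(3, data.frame(driver = 1, follower = 2),
                              lag = 1, noise_prob = 0, n_frames = 3000,
                              seed = i)
  })
  traces <- residue_state_series(contacts, list(n1 = 1, n2 = 2, n3 = 3))
  full <- te_matrix(traces, subsample_fraction = 1, n_repeats = 1, seed = 1)
  # fraction 1, one repeat equals the single full computation
  single <- transfer_entropy(traces$symbols$n1, traces$symbols$n2,
                             lag = 1, seed = 1)
  expect_equal(full$te["n1", "n2"], single$te, tolerance = 1e-12)
  expect_equal(full$te["n1", "n2"], 1, tolerance = 0.05)
  expect_lt(abs(full$te["n2", "n1"]), 0.02)
  expect_equal(diag(full$te), c(n1 = 0, n2 = 0, n3 = 0))
  sub <- te_matrix(traces, subsample_fraction = 0.3, n_repeats = 3, seed = 4)
  sub2 <- te_matrix(traces, subsample_fraction = 0.3, n_repeats = 3, seed = 4)
  expect_identical(sub$te, sub2$te)
  # averaging repeats reduces the spread across seeds
  spread <- function(reps) {
    vals <- vapply(1:8, function(s) {
      te_matrix(traces, subsample_fraction = 0.3, n_repeats = reps,
                seed = 10 * s)$te["n1", "n2"]
    }, numeric(1))
    stats::sd(vals)
  }
  expect_lt(spread(3), spread(1))
})

test_that("HITS scores match brute-force dominant eigenvectors", {
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(runif(25), 5); diag(A) <- 0
    sc <- hits_scores(A)$scores
    ea <- abs(eigen(t(A) %*% A)$vectors[, 1]); ea <- ea / max(ea)
    eh <- abs(eigen(A %*% t(A))$vectors[, 1]); eh <- eh / max(eh)
    expect_lt(max(abs(sc$authority - ea)), 1e-8)
    expect_lt(max(abs(sc$hub - eh)), 1e-8)
  }
  # invariance under uniform rescaling of edge weights
  set.seed(6)
  A <- matrix(runif(25), 5); diag(A) <- 0
  expect_equal(hits_scores(A)$scores, hits_scores(17 * A)$scores,
               tolerance = 1e-10)
})

test_that("HITS handles symmetric and star graph structures", {
  S <- matrix(1, 4, 4); diag(S) <- 0
  sc <- hits_scores(S)$scores
  expect_equal(sc$authority, rep(1, 4), tolerance = 1e-12)
  expect_equal(sc$hub, rep(1, 4), tolerance = 1e-12)
  A3 <- matrix(0, 3, 3); A3[1, 2] <- 1; A3[3, 2] <- 1
  s3 <- hits_scores(A3)$scores
  expect_equal(which.max(s3$authority), 2L)
  expect_equal(s3$authority[2], 1)
  expect_equal(s3$hub[1], s3$hub[3], tolerance = 1e-12)
  expect_error(hits_scores(matrix(0, 3, 3)), "zero")
})

test_that("role classification separates transmitters, receivers, connectors", {
  sc <- structure(list(scores = data.frame(
    node = c("t", "r", "c", "n"),
    authority = c(0.0, 1.0, 1.0, 0.1),
    hub = c(1.0, 0.2, 1.0, 0.1))), class = "node_scores")
  roles <- classify_roles(sc, 0.5, 0.5)
  expect_equal(roles$role, c("transmitter", "receiver", "connector", "none"))
  expect_error(classify_roles(sc, 0, 0.5), "thresholds")
  # planted driver/follower synthetic classifies as transmitter/receiver
  contacts <- lapply(1:6, function(i) {
    simulate_coupled_contacts(2, data.frame(driver = 1, follower = 2),
                              lag = 1, noise_prob = 0.05, n_frames = 4000,
                              seed = 50 + i)
  })
  traces <- residue_state_series(contacts, list(drv = 1, fol = 2))
  tem <- te_matrix(traces, subsample_fraction = 1, n_repeats = 1, seed = 2)
  rl <- classify_roles(hits_scores(tem))
  expect_equal(rl$role[rl$node == "drv"], "transmitter")
  expect_equal(rl$role[rl$node == "fol"], "receiver")
})
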