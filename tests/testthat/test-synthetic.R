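test_that("markov chain generator matches its transition matrix", {
  P <- matrix(c(.9, .1, .2, .8), 2, byrow = TRUE)
  s <- simulate_markov_chain(P, 100000L, seed = 7)
  # analytic stationary occupancy of state 1 is 2/3
  se <- sqrt(2 / 9 / length(s))  # i.i.d. bound; correlation inflates this
  expect_lt(abs(mean(s == 1) - 2 / 3), 10 * se)
  # empirical transition frequencies within 3-sigma binomial bounds
  for (i in 1:2) {
    from <- which(s[-length(s)] == i)
    phat <- mean(s[from + 1L] == 1)
    expect_lt(abs(phat - P[i, 1]),
              3 * sqrt(P[i, 1] * (1 - P[i, 1]) / length(from)))
  }
})

test_that("markov chain generator is deterministic and honours degeneracies", {
  P <- matrix(c(.5, .5, .25, .75), 2, byrow = TRUE)
  expect_identical(simulate_markov_chain(P, 500, seed = 3),
                   simulate_markov_chain(P, 500, seed = 3))
  expect_false(identical(simulate_markov_chain(P, 500, seed = 3),
                         simulate_markov_chain(P, 500, seed = 4)))
  expect_equal(length(unique(simulate_markov_chain(diag(3), 200, seed = 1))), 1L)
  expect_error(simulate_markov_chain(matrix(c(.9, .2, .2, .8), 2), 10), "sum to 1")
})

test_that("multiwell dynamics relax, equilibrate and detect divergence", {
  # single well, no thermal noise: deterministic monotone descent
  x <- simulate_multiwell(matrix(0, 1, 1), depths = 2, widths = 1, kT = 0,
                          D = 1, dt = 0.01, n_frames = 800, x0 = 1.5, seed = 1)
  expect_true(all(diff(x[, 1]) <= 1e-12))
  expect_lt(abs(x[800, 1]), 0.05)
  # symmetric double well: equal long-run occupancy by symmetry
  y <- simulate_multiwell(c(-1, 1), depths = c(4, 4), widths = 0.4,
                          kT = 1, D = 1, dt = 0.01, n_frames = 150000, seed = 2)
  expect_lt(abs(mean(y[, 1] > 0) - 0.5), 0.1)
  expect_gt(sum(diff(sign(y[, 1])) != 0), 50)  # well-sampled barrier
  expect_error(
    simulate_multiwell(c(-1, 1), depths = c(4, 4), widths = .4, dt = 50,
                       n_frames = 100, seed = 1),
    "reduce dt")
})

test_that("latent embedding reproduces the affine map through the featurizer", {
  lat <- simulate_multiwell(c(-1, 1), depths = c(4, 4), widths = 0.4,
                            kT = 1, dt = 0.01, n_frames = 2000, seed = 5)[, 1]
  ens <- embed_latent_trajectory(lat, slope = 3, intercept = 11)
  ds <- build_descriptor_set(ens$topology, selection = c(1L, 2L))
  f <- compute_features(ens, ds)
  expect_lt(max(abs(f$values[[1]][, 1] - (11 + 3 * lat))), 1e-9)
  expect_error(embed_latent_trajectory(lat, slope = 3, intercept = 0),
               "non-positive")
})

test_that("coupled contact process plants the requested directed coupling", {
  x <- simulate_coupled_contacts(3, data.frame(driver = 1, follower = 2),
                                 lag = 1, noise_prob = 0, n_frames = 5000,
                                 seed = 1)
  n <- nrow(x)
  expect_identical(x[2:n, 2], x[1:(n - 1), 1])     # exact delayed copy
  x3 <- simulate_coupled_contacts(2, data.frame(driver = 1, follower = 2),
                                  lag = 3, noise_prob = 0, n_frames = 1000,
                                  seed = 2)
  expect_identical(x3[4:1000, 2], x3[1:997, 1])
  expect_identical(
    simulate_coupled_contacts(2, data.frame(driver = 1, follower = 2),
                              n_frames = 100, seed = 9),
    simulate_coupled_contacts(2, data.frame(driver = 1, follower = 2),
                              n_frames = 100, seed = 9))
  expect_error(
    simulate_coupled_contacts(2, data.frame(driver = 1, follower = 5),
                              n_frames = 10),
    "missing channels")
  expect_error(
    simulate_coupled_contacts(2, data.frame(driver = 1, follower = 2),
                              noise_prob = 0.9, n_frames = 10),
    "noise_prob")
})

test_that("toy complex placements are exact and the empty spec is ligand-only", {
  spec <- data.frame(interaction = c("apolar", "electro_neg"),
                     distance = c(4.4, 3.8))
  tc <- build_toy_complex(spec)
  a <- tc$atoms
  d_apolar <- sqrt(sum((tc$xyz[a$name == "C1", ] -
                          tc$xyz[a$name == "CD1", ])^2))
  expect_equal(d_apolar, 4.4, tolerance = 1e-9)
  lig_n <- which(a$name == "N1" & a$is_ligand)
  od1 <- which(a$name == "OD1" & a$resname == "ASP")
  expect_equal(sqrt(sum((tc$xyz[lig_n, ] - tc$xyz[od1, ])^2)), 3.8,
               tolerance = 1e-9)
  empty <- build_toy_complex(data.frame())
  expect_true(all(empty$atoms$is_ligand))
  expect_error(build_toy_complex(data.frame(interaction = "apolar",
                                            distance = -1)), "positive")
  expect_error(build_toy_complex(data.frame(interaction = "magic",
                                            distance = 3)), "unknown")
})
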