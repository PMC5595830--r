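test_that("committor solves the first-step system with correct boundaries", {
  m <- as_markov_model(chain3())
  q <- committor(m, A = 1, B = 3)
  expect_equal(unname(q$q["2"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(q$q["1"]), 0)
  expect_equal(unname(q$q["3"]), 1)
  # left-right symmetric chain: middle state committor one half
  Ps <- matrix(c(.8, .2, 0, .15, .7, .15, 0, .2, .8), 3, byrow = TRUE)
  qs <- committor(as_markov_model(Ps), A = 1, B = 3)
  expect_equal(unname(qs$q["2"]), 0.5, tolerance = 1e-12)
  expect_error(committor(m, A = 1, B = 1), "disjoint")
  expect_error(committor(m, A = integer(0), B = 3), "non-empty")
})

test_that("committor matches brute-force trajectory statistics", {
  Tm <- metastable4()
  m <- as_markov_model(Tm)
  q <- committor(m, A = 1, B = 4)
  # brute force: fraction of long-trajectory excursions from state 2 that
  # reach 4 before 1
  s <- simulate_markov_chain(Tm, 200000, seed = 13)
  hits <- 0; total <- 0
  i <- 1
  n <- length(s)
  while (i <= n) {
    if (s[i] == 2) {
      j <- i + 1
      while (j <= n && !(s[j] %in% c(1, 4))) j <- j + 1
      if (j <= n) { total <- total + 1; hits <- hits + (s[j] == 4) }
      i <- j
    }
    i <- i + 1
  }
  phat <- hits / total
  se <- sqrt(phat * (1 - phat) / total)
  expect_lt(abs(unname(q$q["2"]) - phat), 3 * se + 1e-6)
})

test_that("reactive flux is conserved and matches hand evaluation", {
  m <- as_markov_model(chain3())
  q <- committor(m, A = 1, B = 3)
  fx <- reactive_flux(m, q)
  # conservation: flux out of A equals flux into B
  expect_equal(sum(fx$gross[1, ]), sum(fx$gross[, 3]), tolerance = 1e-10)
  # hand evaluation of f_ij = pi_i (1-q_i) T_ij q_j
  pi <- m$pi; Tm <- m$T; qv <- unname(q$q)
  f12_hand <- pi[1] * (1 - qv[1]) * Tm[1, 2] * qv[2]
  expect_equal(fx$gross[1, 2], f12_hand, tolerance = 1e-14)
  expect_equal(fx$total_flux, sum(fx$gross[1, ]), tolerance = 1e-14)
  # net flux antisymmetric part is non-negative and conserved at node 2
  expect_true(all(fx$net >= 0))
  expect_equal(sum(fx$net[, 2]) - sum(fx$net[2, ]), 0, tolerance = 1e-10)
  # unreachable B: remove all edges into state 3
  Pu <- matrix(c(.8, .2, 0, .3, .7, 0, 0, .3, .7), 3, byrow = TRUE)
  mu <- suppressWarnings(as_markov_model(Pu))
  qu <- committor(mu, A = 1, B = 3)
  fxu <- reactive_flux(mu, qu)
  expect_equal(fxu$total_flux, 0, tolerance = 1e-12)
})

test_that("pathway decomposition splits parallel channels by their flux", {
  net <- matrix(0, 4, 4)
  net[1, 2] <- 2; net[2, 4] <- 2; net[1, 3] <- 1; net[3, 4] <- 1
  fx <- structure(list(macro_net = net, macro_A = 1, macro_B = 4),
                  class = "flux_network")
  pd <- decompose_pathways(fx)
  expect_equal(pd$pathways$fraction, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(pd$pathways$pathway, c("1 -> 2 -> 4", "1 -> 3 -> 4"))
  expect_lte(sum(pd$pathways$fraction), 1 + 1e-9)
  # single chain: one pathway, full flux
  net2 <- matrix(0, 3, 3); net2[1, 2] <- 1; net2[2, 3] <- 1
  fx2 <- structure(list(macro_net = net2, macro_A = 1, macro_B = 3),
                   class = "flux_network")
  pd2 <- decompose_pathways(fx2)
  expect_equal(nrow(pd2$pathways), 1L)
  expect_equal(pd2$pathways$fraction, 1)
  # residual flux that cannot reach B is an upstream error
  net3 <- matrix(0, 4, 4)
  net3[1, 2] <- 1; net3[2, 3] <- 2; net3[3, 2] <- 1  # dead-end cycle weight
  fx3 <- structure(list(macro_net = net3, macro_A = 1, macro_B = 4),
                   class = "flux_network")
  expect_error(decompose_pathways(fx3), "cannot reach B|zero")
})

test_that("MFPT matches first-step analysis and brute-force simulation", {
  P <- matrix(c(.9, .1, .2, .8), 2, byrow = TRUE)
  m <- as_markov_model(P, lag_frames = 2L, frame_interval_ns = 0.5)
  r <- mfpt(m, 1, 2)
  expect_equal(r$steps, 10)
  expect_equal(r$frames, 20)
  expect_equal(r$ns, 10)
  expect_equal(mfpt(m, 1, 1)$steps, 0)
  # brute force hitting times
  s <- simulate_markov_chain(P, 300000, seed = 17)
  starts <- which(s[-length(s)] == 2 & s[-1] == 1) + 1L  # entries into state 1
  times <- c()
  for (st in starts) {
    j <- st
    while (j <= length(s) && s[j] != 2) j <- j + 1
    if (j <= length(s)) times <- c(times, j - st)
  }
  se <- stats::sd(times) / sqrt(length(times))
  expect_lt(abs(mean(times) - 10), 3 * se)
  # monotonicity: increasing the direct source->target probability cannot
  # slow the transition
  base <- mfpt(as_markov_model(chain3()), 1, 3)$steps
  for (boost in c(0.05, 0.15)) {
    P3 <- chain3()
    P3[1, 3] <- P3[1, 3] + boost
    P3[1, 1] <- P3[1, 1] - boost
    faster <- mfpt(suppressWarnings(as_markov_model(P3)), 1, 3)$steps
    expect_lte(faster, base + 1e-9)
  }
})

test_that("macrostate MFPT matrix has zero diagonal, non-negative entries", {
  Tm <- metastable4()
  m <- as_markov_model(Tm)
  mc <- pcca_lump(m, 2)
  M <- mfpt_matrix(m, mc)
  expect_equal(diag(M), c(0, 0))
  expect_true(all(M >= 0))
  expect_gt(M[1, 2], 1)  # metastable blocks take many steps to swap
})

test_that("coarse-grained flux is invariant to macrostate relabeling", {
  Tm <- metastable4()
  m <- as_markov_model(Tm)
  mc <- pcca_lump(m, 2)
  q <- committor(m, A = macro_members_test(mc, 1), B = macro_members_test(mc, 2))
  fx <- reactive_flux(m, q, mc)
  # relabeled copy of the macrostate model
  mc2 <- mc
  mc2$assignment <- 3L - mc$assignment
  mc2$macro_pi <- rev(mc$macro_pi)
  fx2 <- reactive_flux(m, q, mc2)
  expect_equal(sum(fx$macro_net), sum(fx2$macro_net), tolerance = 1e-14)
  expect_equal(fx$macro_net[1, 2], fx2$macro_net[2, 1], tolerance = 1e-14)
  # DOT export writes a parseable edge list
  p <- tempfile(fileext = ".dot")
  write_flux_dot(fx, p)
  expect_true(any(grepl("->", readLines(p))))
})
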