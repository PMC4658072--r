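# Label sequences here use 1-based state labels; the spec's [0,0,1,1]
# example maps to c(1,1,2,2).

test_that("sliding-window transition counts match hand enumeration", {
  expect_equal(count_transitions(c(1L, 1L, 2L, 2L), lag = 1),
               matrix(c(1, 0, 1, 1), 2, 2))        # C[1,1]=1 C[1,2]=1 C[2,2]=1
  expect_equal(count_transitions(c(1L, 1L, 2L, 2L), lag = 2),
               matrix(c(0, 0, 2, 0), 2, 2))        # both windows 1 -> 2
  expect_equal(count_transitions(rep(3L, 50), lag = 7)[3, 3], 43)
  # trajectories never concatenated across boundaries
  C <- count_transitions(list(c(1L, 2L), c(2L, 1L)), lag = 1)
  expect_equal(C, matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(count_transitions(list(1:2), lag = 5), "shorter than the lag")
})

test_that("row normalization and stationary vector solve small cases exactly", {
  m <- estimate_markov_model(matrix(c(9, 1, 1, 9), 2, 2, byrow = TRUE), lag = 1)
  expect_equal(m$transition_matrix,
               matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE))
  expect_equal(m$stationary, c(0.5, 0.5))
  m2 <- estimate_markov_model(matrix(c(8, 2, 1, 3), 2, 2, byrow = TRUE), lag = 1)
  expect_equal(m2$transition_matrix[1, ], c(0.8, 0.2))
  expect_equal(m2$transition_matrix[2, ], c(0.25, 0.75))
  expect_equal(m2$stationary, c(5, 4) / 9, tolerance = 1e-12)  # pi T = pi by hand
  expect_true(abs(m2$eigenvalues[1] - 1) < 1e-12)
  expect_equal(as.numeric(m2$stationary %*% m2$transition_matrix),
               m2$stationary, tolerance = 1e-10)
})

test_that("connectivity restriction keeps the largest strongly connected block", {
  C <- matrix(0, 5, 5)
  C[1:3, 1:3] <- 5          # 3-state block
  C[4, 5] <- 3; C[5, 4] <- 3  # 2-state block
  m <- estimate_markov_model(C, lag = 1)
  expect_equal(m$active_set, 1:3)
  expect_equal(m$n_discarded_counts, 6)
  # one-way edge does not merge the blocks
  C[3, 4] <- 1
  expect_equal(estimate_markov_model(C, lag = 1)$active_set, 1:3)
})

test_that("reversible estimator satisfies detailed balance", {
  set.seed(2)
  C <- matrix(rpois(16, 30), 4, 4)
  m <- estimate_markov_model(C, lag = 1, reversible = TRUE)
  Tm <- m$transition_matrix
  pi <- m$stationary
  flux <- diag(pi) %*% Tm
  expect_equal(flux, t(flux), tolerance = 1e-8)
  expect_true(all(abs(Im(m$eigenvalues)) < 1e-12))
})

test_that("propagation matches direct multiplication and conserves mass", {
  Tm <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  m <- estimate_markov_model(Tm * 1000, lag = 1)
  expect_equal(propagate(m, c(1, 0), 0), c(1, 0))
  expect_equal(propagate(m, c(1, 0), 1), c(0.9, 0.1))
  p <- propagate(m, c(1, 0), 10000)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p, m$stationary, tolerance = 1e-6)  # spectral decay to pi
  expect_error(propagate(m, c(1, 0, 0), 1), "dimension")
})

test_that("implied timescales follow the closed form and flag bad modes", {
  # chain with mu2 = 0.7: tau2 = -tau / ln 0.7
  Tm <- matrix(c(0.85, 0.15, 0.15, 0.85), 2, 2, byrow = TRUE)
  ts <- timescales_from_eigenvalues(eigen(Tm)$values, lag_time = 3, k_modes = 1)
  expect_equal(ts$tau, -3 / log(0.7), tolerance = 1e-12)
  # reducible chain: mu2 = 1 -> infinite timescale, flagged
  ts2 <- timescales_from_eigenvalues(c(1, 1, 0.5), lag_time = 1, k_modes = 2)
  expect_equal(ts2$flag, c("unit", "ok"))
  expect_equal(ts2$tau[1], Inf)
  # negative eigenvalue flagged, not an exception
  ts3 <- timescales_from_eigenvalues(c(1, -0.2), lag_time = 1, k_modes = 1)
  expect_equal(ts3$flag, "nonpositive")
  expect_true(is.na(ts3$tau))
})

test_that("timescales estimated from sampled data level off at the truth", {
  Tm <- matrix(c(0.95, 0.04, 0.01,
                 0.03, 0.90, 0.07,
                 0.02, 0.08, 0.90), 3, 3, byrow = TRUE)
  true_tau <- -1 / log(Mod(eigen(Tm)$values[2]))
  s <- sample_discrete_chain(Tm, 1e5, seed = 17)
  curve <- implied_timescales(list(s), lags = c(1L, 2L, 4L), k_modes = 1)
  # markovian data: flat across lags, near the true relaxation time
  expect_true(all(abs(curve$tau / true_tau - 1) < 0.10))
  expect_error(implied_timescales(list(s), lags = c(4L, 2L)), "increasing")
})

test_that("Chapman-Kolmogorov agrees on Markov data at n = 1 by construction", {
  Tm <- random_ergodic_chain(4, seed = 3)
  s <- sample_discrete_chain(Tm, 2e5, seed = 4)
  C <- count_transitions(list(s), 2, n_states = 4)
  m <- estimate_markov_model(C, lag = 2)
  ck <- chapman_kolmogorov(list(s), m, multiples = 1:6, n_states_tested = 4)
  n1 <- ck[ck$n == 1, ]
  expect_equal(n1$predicted, n1$observed, tolerance = 1e-12)
  within3 <- with(ck[!ck$missing, ], abs(predicted - observed) <= 3 * se)
  expect_gte(mean(within3), 0.95)
})

test_that("Chapman-Kolmogorov exposes a hidden-state non-Markov process", {
  # 4 hidden states observed through 2 labels; the deep state 1 makes the
  # observed A-lifetime strongly non-exponential
  Th <- rbind(c(0.99, 0.01, 0.00, 0.00),
              c(0.05, 0.75, 0.20, 0.00),
              c(0.00, 0.20, 0.75, 0.05),
              c(0.00, 0.00, 0.01, 0.99))
  hidden <- sample_discrete_chain(Th, 5e5, seed = 6)
  obs <- ifelse(hidden <= 2, 1L, 2L)
  C <- count_transitions(list(obs), 1, n_states = 2)
  m <- estimate_markov_model(C, lag = 1)
  ck <- chapman_kolmogorov(list(obs), m, multiples = c(1, 5, 8, 10),
                           n_states_tested = 2)
  late <- ck[ck$n >= 5 & !ck$missing, ]
  expect_true(all(abs(late$predicted - late$observed) > 3 * late$se))
})

test_that("estimation error of T decays like n^(-1/2)", {
  Tm <- random_ergodic_chain(3, seed = 10)
  err_at <- function(n, seed) {
    s <- sample_discrete_chain(Tm, n, seed = seed)
    C <- count_transitions(list(s), 1, n_states = 3)
    max(abs(C / rowSums(C) - Tm))
  }
  errs <- c(err_at(1e4, 1), err_at(1e5, 2), err_at(1e6, 3))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 3)  # ~10x fewer than sqrt(100) but monotone and strong
})
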