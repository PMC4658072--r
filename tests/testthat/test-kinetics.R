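two_state_model <- function(p, lag_time = 1) {
  Tm <- rbind(c(1 - p, p), c(p, 1 - p))
  m <- estimate_markov_model(Tm * 1e9, lag = 1, lag_time = lag_time)
  m
}

test_that("MFPT linear solve: boundary condition and geometric closed form", {
  m <- two_state_model(0.1, lag_time = 3)
  expect_equal(mfpt_solve(m, source = 2, target = 2), 0)
  expect_equal(mfpt_solve(m, source = 1, target = 2), 3 / 0.1, tolerance = 1e-9)
  # the defining recursion f = P (tau + f) holds on return
  val <- mfpt_solve(m, 1, 2, full = TRUE)
  f <- attr(val, "f")
  Tm <- m$transition_matrix
  resid <- f[1] - sum(Tm[1, ] * (3 + f))
  expect_lt(abs(resid), 1e-9)
})

test_that("unreachable targets give an infinite MFPT with a warning", {
  Tm <- rbind(c(0.9, 0.1, 0), c(0.1, 0.9, 0), c(0.1, 0.1, 0.8))
  m <- structure(list(transition_matrix = Tm, stationary = c(0.45, 0.45, 0.1),
                      lag = 1L, lag_time = 1, active_set = 1:3,
                      eigenvalues = eigen(Tm)$values, reversible = FALSE),
                 class = "markov_model")
  expect_warning(v <- mfpt_solve(m, source = 1, target = 3), "not reachable")
  expect_equal(v, Inf)
})

test_that("MFPT solve matches Monte-Carlo first-passage means on random chains", {
  for (seed in 1:3) {
    Tm <- random_ergodic_chain(5, seed = 200 + seed)
    m <- estimate_markov_model(Tm * 1e9, lag = 1)
    s <- sample_discrete_chain(Tm, 3e5, seed = seed)
    for (target in c(2, 5)) {
      for (source in setdiff(c(1, 3), target)) {
        fp <- collect_first_passages(s, source, target)
        se <- stats::sd(fp$times) / sqrt(length(fp$times))
        expect_lt(abs(mean(fp$times) - mfpt_solve(m, source, target)),
                  3 * se + 1e-9)
      }
    }
  }
})

test_that("first-passage collection follows the declared event convention", {
  # [A,A,B]: one passage of 2 lags from the first frame
  expect_equal(collect_first_passages(c(1, 1, 2), 1, 2)$times, 2)
  # no source visits: empty sample
  expect_length(collect_first_passages(c(2, 2, 2), 1, 2)$times, 0)
  # [A,C,A,C,B]: re-entering the source does not reset the open passage
  expect_equal(collect_first_passages(c(1, 3, 1, 3, 2), 1, 2)$times, 4)
  # passage unfinished at the end is discarded
  expect_length(collect_first_passages(c(1, 3, 3), 1, 2)$times, 0)
  # consecutive passages: restart only after completion
  expect_equal(collect_first_passages(c(1, 2, 1, 1, 2), 1, 2)$times, c(1, 2))
  # tau scales the reported times
  expect_equal(collect_first_passages(c(1, 1, 2), 1, 2, tau = 3)$times, 6)
  expect_error(collect_first_passages(c(1, 2), 1, 1), "disjoint")
})

test_that("Poisson log-count regression recovers an exponential mean", {
  set.seed(8)
  x <- rexp(1e4, rate = 1 / 40)
  fit <- fit_fpt_poisson(x)
  expect_equal(fit$mean, 40, tolerance = 0.05)
  expect_gt(fit$r2, 0.95)
  # truncation choices barely move genuinely exponential data
  fit_wide <- fit_fpt_poisson(x, window = c(0, 1), refine_window = FALSE)
  expect_lt(abs(fit_wide$mean - fit$mean) / fit$mean, 0.10)
  # arithmetic mean agrees with the fitted mean within 2 SE
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(fit$mean - mean(x)), 2 * se + 0.05 * mean(x))
})

test_that("degenerate passage samples are rejected with diagnostics", {
  expect_error(fit_fpt_poisson(rep(7, 100)), "degenerate")
  expect_error(fit_fpt_poisson(rexp(10)), "too few")
  set.seed(1)
  expect_error(fit_fpt_poisson(c(rexp(100, 1))[1:60] * 0 + rep(c(1, 2), 30)),
               "non-negative slope|too few occupied")
})

test_that("MC replica estimate is consistent with the linear solve", {
  pl <- planted_block_chain(c(3, 3, 3), coupling = 0.02, seed = 40)
  m <- suppressWarnings(estimate_markov_model(pl$T * 1e9, lag = 1))
  lump <- suppressWarnings(pcca_plus(m, 3))
  # identify the lumped labels of the planted blocks
  b1 <- lump$crisp_map[1]; b2 <- lump$crisp_map[4]
  est <- suppressWarnings(
    mfpt_mc(m, lump, source = b1, target = b2, n_replicas = 5,
            steps_per_replica = 2e5, seed = 3))
  coarse <- coarse_grain(m, lump)
  solve_val <- mfpt_solve(coarse, b1, b2)
  expect_lt(abs(est$replica_average - solve_val),
            3 * est$standard_error + 0.15 * solve_val)
  expect_equal(length(est$replica_means), 5)
})

test_that("upper bound dominates the macro solve and collapses for singletons", {
  # trap: microstate 2 inside the source macro is slow to leave
  Tm <- rbind(c(0.70, 0.10, 0.20),
              c(0.01, 0.98, 0.01),
              c(0.20, 0.05, 0.75))
  m <- estimate_markov_model(Tm * 1e9, lag = 1)
  crisp <- c(1L, 1L, 2L)
  ub <- mfpt_upper_bound(m, crisp, 1, 2)
  cg <- coarse_grain(m, crisp)
  expect_gte(ub, mfpt_solve(cg, 1, 2) - 1e-9)
  # perfectly lumpable: fast within-macro mixing, slow cross transitions
  pl <- planted_block_chain(c(4, 4), coupling = 1e-3, seed = 50)
  m2 <- suppressWarnings(estimate_markov_model(pl$T * 1e9, lag = 1))
  ub2 <- mfpt_upper_bound(m2, pl$block, 1, 2)
  cg2 <- coarse_grain(m2, pl$block)
  expect_equal(ub2, mfpt_solve(cg2, 1, 2), tolerance = 0.10)
  # singleton macrostates: bound equals the solve exactly
  Tm3 <- random_ergodic_chain(3, seed = 60)
  m3 <- estimate_markov_model(Tm3 * 1e9, lag = 1)
  expect_equal(mfpt_upper_bound(m3, 1:3, 1, 3), mfpt_solve(m3, 1, 3),
               tolerance = 1e-12)
})

test_that("MC estimate converges toward the solve as sampling grows", {
  Tm <- rbind(c(0.95, 0.05), c(0.02, 0.98))
  m <- estimate_markov_model(Tm * 1e9, lag = 1)
  truth <- mfpt_solve(m, 1, 2)
  err <- vapply(c(1e4, 1e6), function(n) {
    s <- sample_discrete_chain(Tm, n, seed = 77)
    abs(mean(collect_first_passages(s, 1, 2)$times) - truth)
  }, 0)
  expect_lt(err[2], err[1])
})
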