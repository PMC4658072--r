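test_that("flat potential with zero diffusion yields a constant trajectory", {
  pot <- potential_spec(centers = 0, depths = 1e-12, widths = 1, diffusion = 0,
                        wall_lo = -100, wall_hi = 100)
  tr <- simulate_langevin(pot, n_steps = 100, dt = 0.01, seed = 1, start = 0.7)
  expect_true(all(tr$frames[, 1] == 0.7))
})

test_that("harmonic well sampling reproduces the Boltzmann variance kT/k", {
  pot <- potential_spec(centers = 0, depths = 1e-12, widths = 1,
                        harmonic_k = 2, kT = 1.5,
                        wall_lo = -50, wall_hi = 50)
  tr <- simulate_langevin(pot, n_steps = 1e6, dt = 0.005, seed = 11, start = 0)
  expect_equal(var(tr$frames[, 1]), 1.5 / 2, tolerance = 0.05)
})

test_that("symmetric double well splits occupancy 50/50 within counting error", {
  pot <- potential_spec(centers = c(-1.5, 1.5), depths = c(3, 3),
                        widths = c(0.6, 0.6))
  tr <- simulate_langevin(pot, n_steps = 2e6, dt = 0.005, seed = 5,
                          start = -1.5, save_every = 5)
  frac_right <- mean(tr$frames[, 1] > 0)
  # effective sample size ~ number of barrier crossings, not frames
  lab <- sign(tr$frames[, 1])
  n_cross <- sum(diff(lab) != 0)
  expect_gt(n_cross, 100)
  expect_lt(abs(frac_right - 0.5), 3 / sqrt(n_cross))
})

test_that("fixed seed means bit-identical trajectories, different seeds differ", {
  pot <- potential_spec(centers = c(-1, 1), depths = c(2, 2), widths = c(0.5, 0.5))
  a <- simulate_langevin(pot, 5000, dt = 0.005, seed = 3, start = 0)
  b <- simulate_langevin(pot, 5000, dt = 0.005, seed = 3, start = 0)
  c <- simulate_langevin(pot, 5000, dt = 0.005, seed = 4, start = 0)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, c$frames))
})

test_that("step-size guard rejects drift larger than a tenth of a basin width", {
  pot <- potential_spec(centers = 0, depths = 30, widths = 0.1)
  expect_error(simulate_langevin(pot, 100, dt = 0.05, seed = 1, start = 0.12),
               "time step too large")
})

test_that("stiff-spring low-noise pull tracks the bias-center path", {
  # near-zero kT with small D: large mobility, negligible thermal spread
  # (sqrt(kT/k) ~ 3e-4), so the particle rides the moving restraint center
  pot <- potential_spec(centers = 0, depths = 1e-12, widths = 1,
                        kT = 1e-6, diffusion = 1e-3,
                        wall_lo = -100, wall_hi = 100)
  pull <- pull_spec(direction = 1, spring_constant = 10, pull_rate = 0.5)
  tr <- simulate_steered_pull(pot, pull, n_steps = 2000, dt = 5e-5, seed = 1,
                              start = 0)
  expect_lt(max(abs(tr$frames[, 1] - tr$bias_record[, 1])), 0.01)
})

test_that("pull with zero-ish rate is restrained equilibrium about the start", {
  pot <- potential_spec(centers = 0, depths = 1e-12, widths = 1,
                        wall_lo = -50, wall_hi = 50)
  pull <- pull_spec(direction = 1, spring_constant = 20, pull_rate = 1e-12)
  tr <- simulate_steered_pull(pot, pull, n_steps = 2e5, dt = 0.005, seed = 9,
                              start = 2)
  x <- tr$frames[, 1]
  expect_equal(mean(x), 2, tolerance = 0.05)      # umbrella at fixed center
  expect_equal(var(x), 1 / 20, tolerance = 0.2)   # kT/k about the center
})

test_that("a pull crosses both barriers of the triple-well benchmark", {
  bs <- make_benchmark_system(run_oracle = FALSE)
  pot <- bs$potential
  pull <- pull_spec(direction = c(1, 0), spring_constant = 10, pull_rate = 0.01)
  span <- diff(range(pot$centers[, 1])) + 0.5
  tr <- simulate_steered_pull(pot, pull, n_steps = ceiling(span / 0.01 / 0.002),
                              dt = 0.002, seed = 2,
                              start = c(pot$centers[1, 1], 0), save_every = 100)
  x <- tr$frames[, 1]
  expect_gt(max(x), bs$boundaries[2])   # reached beyond the second barrier
  expect_lt(min(x), bs$boundaries[1])   # started before the first
})

test_that("adaptive seeding returns the requested picks per cluster", {
  # a dense pull path: 20 clusters x 5 picks = exactly 100 starts
  path <- trajectory(matrix(seq(0, 10, length.out = 2000), ncol = 1), 1)
  starts <- adaptive_seed(list(path), n_clusters = 20, picks_per_cluster = 5L,
                          seed = 1)
  expect_equal(nrow(starts), 100L)
  expect_equal(sort(unique(attr(starts, "cluster"))), 1:20)
  # reproducibility
  starts2 <- adaptive_seed(list(path), n_clusters = 20, picks_per_cluster = 5L,
                           seed = 1)
  expect_identical(starts, starts2)
  # on stochastic data the count is sum over clusters of min(picks, size)
  pot <- potential_spec(centers = c(-1, 1), depths = c(2, 2), widths = c(0.5, 0.5))
  pulls <- lapply(1:3, function(i)
    simulate_langevin(pot, 2000, dt = 0.005, seed = i, start = 0, save_every = 10))
  km <- kcenter(do.call(rbind, lapply(pulls, function(tr) tr$frames)), k = 20)
  expected_n <- sum(pmin(5L, tabulate(km$assignments, 20)))
  suppressWarnings(
    s3 <- adaptive_seed(pulls, n_clusters = 20, picks_per_cluster = 5L, seed = 1))
  expect_equal(nrow(s3), expected_n)
})

test_that("adaptive seeding keeps well-separated groups apart and handles small clusters", {
  set.seed(42)
  tr1 <- trajectory(matrix(rnorm(100, mean = 0, sd = 0.1), ncol = 1), 1)
  tr2 <- trajectory(matrix(rnorm(100, mean = 50, sd = 0.1), ncol = 1), 1)
  starts <- adaptive_seed(list(tr1, tr2), n_clusters = 2, picks_per_cluster = 10L,
                          seed = 2)
  cl <- attr(starts, "cluster")
  expect_true(all(abs(starts[cl == cl[1], 1] - starts[1, 1]) < 25))
  # brute-force: each group's starts must come from that group's value range
  expect_setequal(round(sort(tapply(starts[, 1], cl, mean)) / 50), c(0, 1))
  # cluster smaller than the requested picks: take all, warn
  tiny <- trajectory(matrix(c(0, 0.01, 100, 100.01), ncol = 1), 1)
  suppressWarnings(expect_warning(
    s2 <- adaptive_seed(list(tiny), n_clusters = 2, picks_per_cluster = 5L, seed = 1),
    "taking all"))
  expect_equal(nrow(s2), 4L)
})

test_that("discrete chain sampler honors degenerate and stochastic matrices", {
  expect_equal(sample_discrete_chain(diag(3), 10, seed = 1, start_state = 2),
               rep(2L, 11))
  P <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(sample_discrete_chain(P, 6, seed = 1, start_state = 1),
               c(1L, 2L, 3L, 1L, 2L, 3L, 1L))
  bad <- matrix(c(0.9, 0.2, 0.1, 0.9), 2, 2)
  expect_error(sample_discrete_chain(bad, 10, seed = 1), "sum to 1")
})

test_that("empirical transition frequencies converge to the chain matrix", {
  Tm <- random_ergodic_chain(3, seed = 21)
  s <- sample_discrete_chain(Tm, 1e6, seed = 8)
  C <- count_transitions(list(s), 1, n_states = 3)
  That <- C / rowSums(C)
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt(Tm[i, j] * (1 - Tm[i, j]) / sum(C[i, ]))
    expect_lt(abs(That[i, j] - Tm[i, j]), 3 * se + 1e-12)
  }
})

test_that("benchmark construction hits requested populations and rejects bad ones", {
  bs <- make_benchmark_system(populations = c(1/3, 1/3, 1/3), mfpt_ratio = 1.05,
                              run_oracle = FALSE)
  expect_equal(unname(bs$tuned$boltzmann_populations), rep(1/3, 3),
               tolerance = 0.02)
  expect_error(make_benchmark_system(populations = c(0.999, 5e-4, 5e-4)),
               "untunable")
  expect_error(make_benchmark_system(populations = c(0.5, 0.4, 0.2)), "sum to 1")
})
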