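test_that("uniform samples give a flat profile within multinomial noise", {
  set.seed(1)
  n <- 1e5
  prof <- density_1d(runif(n), bins = 10, range = c(0, 1))
  expect_equal(sum(prof$counts), n)
  p0 <- 1 / 10
  se <- sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(prof$counts / n - p0) < 3 * se))
  # -ln P spread is correspondingly tiny and the minimum is shifted to 0
  expect_equal(min(prof$neg_log_p, na.rm = TRUE), 0)
  expect_lt(max(prof$neg_log_p, na.rm = TRUE), 0.1)
})

test_that("single occupied bin is zero there and masked elsewhere", {
  prof <- density_1d(rep(2.5, 100), bins = 5, range = c(0, 10))
  occupied <- which(!prof$mask)
  expect_length(occupied, 1)
  expect_equal(prof$neg_log_p[occupied], 0)
  expect_true(all(is.na(prof$neg_log_p[prof$mask])))
  # identical values with automatic bins degrade gracefully
  prof2 <- density_1d(rep(1, 50), bins = 4)
  expect_equal(sum(!prof2$mask), 1)
})

test_that("benchmark escape profile shows three local minima at the basins", {
  bs <- make_benchmark_system(run_oracle = FALSE)
  tr <- simulate_langevin(bs$potential, n_steps = 2e6, dt = 0.002, seed = 2,
                          start = c(3, 0), save_every = 10)
  prof <- density_1d(tr$frames[, 1], bins = 60)
  nlp <- prof$neg_log_p
  centers <- prof$centers
  near <- function(x, w = 0.75) min(nlp[abs(centers - x) < w], na.rm = TRUE)
  # each basin is a local minimum of -ln P, separated by higher barriers
  b <- bs$boundaries
  expect_lt(near(3), near(b[1], 0.4))
  expect_lt(near(6), near(b[1], 0.4))
  expect_lt(near(6), near(b[2], 0.4))
  expect_lt(near(10), near(b[2], 0.4))
})

test_that("2-D maps: independence is flat, perfect correlation is diagonal", {
  set.seed(9)
  n <- 2e4
  x <- runif(n)
  flat <- density_2d(x, runif(n), bins = 5, range = list(c(0, 1), c(0, 1)))
  expect_equal(sum(flat$counts), n)
  p0 <- 1 / 25
  expect_true(all(abs(flat$counts / n - p0) < 4 * sqrt(p0 * (1 - p0) / n)))
  diagd <- density_2d(x, x, bins = 5, range = list(c(0, 1), c(0, 1)))
  expect_equal(sum(diag(diagd$counts)), n)   # all mass on the diagonal band
  expect_true(all(diagd$mask[upper.tri(diagd$mask)]))
})

test_that("identical windows have zero divergence; stationary data near zero", {
  pot <- potential_spec(centers = 0, depths = 1e-12, widths = 1, harmonic_k = 1,
                        wall_lo = -30, wall_hi = 30)
  ens <- lapply(1:4, function(i)
    simulate_langevin(pot, 4e4, dt = 0.005, seed = i, start = 0, save_every = 10))
  total_t <- 4e4 * 0.005
  same <- convergence_blocks(ens, 1, windows = list(c(0, total_t), c(0, total_t)),
                             bins = 30)
  expect_equal(same$divergence, 0, tolerance = 1e-12)
  stat <- convergence_blocks(ens, 1,
                             windows = list(c(0.25 * total_t, total_t),
                                            c(0.5 * total_t, total_t)),
                             bins = 30)
  expect_lt(stat$divergence, 0.005)  # resampling noise floor
  expect_error(convergence_blocks(ens, 1, windows = list(c(1e5, 2e5))),
               "no frames")
})

test_that("dropping burn-in data lowers the block divergence", {
  # trajectories start far from equilibrium (at +4 in a well at 0)
  pot <- potential_spec(centers = 0, depths = 3, widths = 1,
                        wall_lo = -8, wall_hi = 8)
  ens <- lapply(1:6, function(i)
    simulate_langevin(pot, 4e4, dt = 0.002, seed = 10 + i, start = 4,
                      save_every = 10))
  total_t <- 4e4 * 0.002
  w_late <- c(0.5 * total_t, total_t)
  with_burnin <- convergence_blocks(ens, 1, windows = list(c(0, total_t), w_late),
                                    bins = 30)
  without <- convergence_blocks(ens, 1,
                                windows = list(c(0.25 * total_t, total_t), w_late),
                                bins = 30)
  expect_lt(without$divergence, with_burnin$divergence)
})

test_that("profiles are invariant to sample order and conserve counts", {
  set.seed(4)
  x <- rnorm(5000)
  a <- density_1d(x, bins = 20)
  b <- density_1d(sample(x), bins = 20)
  expect_equal(a$counts, b$counts)
  expect_equal(a$neg_log_p, b$neg_log_p)
  # total probability is conserved: counts recoverable from -ln P + shift
  occ <- !a$mask
  shift <- -log(max(a$counts) / a$n_samples)  # value at the deepest bin
  recovered <- exp(-(a$neg_log_p[occ] + shift)) * a$n_samples
  expect_equal(round(recovered), a$counts[occ])
})
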