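# Shared fixtures: random ergodic chains, planted metastable chains, and
# small geometric frames, all built in code under fixed seeds.

# Random ergodic row-stochastic matrix (all entries positive).
random_ergodic_chain <- function(n, seed) {
  set.seed(seed)
  Tm <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  Tm / rowSums(Tm)
}

# Block-metastable chain: `sizes` microstates per block, uniform within-block
# mixing, total cross-block probability `coupling` spread over foreign states.
planted_block_chain <- function(sizes, coupling, seed) {
  set.seed(seed)
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  Tm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    same <- block == block[i]
    w_same <- stats::runif(sum(same), 0.5, 1)
    w_other <- stats::runif(sum(!same), 0.5, 1)
    Tm[i, same] <- (1 - coupling) * w_same / sum(w_same)
    Tm[i, !same] <- coupling * w_other / sum(w_other)
  }
  list(T = Tm, block = block)
}

# Random rigid transform applied to a 3-D point set.
random_rigid_transform <- function(pts, seed) {
  set.seed(seed)
  ang <- stats::runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0), c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  shift <- stats::runif(3, -5, 5)
  sweep(pts %*% t(R), 2, shift, `+`)
}

# Rotation matrix from three Euler angles (used by the brute-force
# superposition oracle; independent of the Kabsch code path).
euler_rotation <- function(a, b, c) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

# Brute-force minimum alignment RMSD over rigid transforms: centroids fix the
# translation; rotations are scanned on an Euler grid and refined locally.
grid_search_rmsd <- function(mobile, ref, n_grid = 13) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(ref, 2, colMeans(ref))
  rmsd_of <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((mc %*% t(R) - rc)^2)))
  }
  grid <- seq(-pi, pi, length.out = n_grid)
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in grid) for (b in grid) for (c in grid) {
    v <- rmsd_of(c(a, b, c))
    if (v < best) { best <- v; best_ang <- c(a, b, c) }
  }
  opt <- stats::optim(best_ang, rmsd_of, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  opt$value
}
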