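# Synthetic trajectory generation: multi-basin overdamped Langevin dynamics,
# steered pulls, adaptive seeding, and exact discrete Markov chains used as
# ground truth for the estimation stack.

#' Define a multi-basin potential
#'
#' The potential is a sum of Gaussian wells, per-coordinate harmonic terms, an
#' optional bilinear coupling between an "escape" coordinate and a "gate"
#' coordinate, and flat-bottomed harmonic walls confining the domain:
#' \deqn{U(x) = -\sum_b d_b e^{-|x-c_b|^2/2w_b^2} + \tfrac12\sum_j k_j x_j^2 +
#'   g\,(x_{esc}-x_0)\,x_{gate} + k_{wall}\sum_j \max(0, |x_j|-L_j)^2}
#' All quantities are in reduced units: energies in kT (so `kT = 1` by
#' default), lengths O(1), and time via the diffusion coefficient.
#'
#' @param centers numeric matrix (n_basins x n_dims) of basin centers, or a
#'   vector for one-dimensional potentials.
#' @param depths,widths depths: numeric vector, one well depth (in `kT`
#'   units) per basin. widths: Gaussian standard deviations — either one
#'   isotropic value per basin, or an `n_basins x n_dims` matrix of
#'   per-coordinate widths (a very large width makes a well flat along that
#'   coordinate).
#' @param kT thermal energy (> 0).
#' @param diffusion diffusion coefficient D (> 0), length^2/time.
#' @param harmonic_k per-coordinate harmonic spring constants (default 0).
#' @param gate_coupling bilinear coupling strength g tying the gate coordinate
#'   to the escape coordinate; 0 disables the term.
#' @param escape_index,gate_index coordinate indices entering the bilinear
#'   coupling term.
#' @param gate_ref reference value of the escape coordinate about which the
#'   coupling acts, so the gate is unbiased when the escape coordinate sits at
#'   `gate_ref`.
#' @param wall_lo,wall_hi per-coordinate domain bounds beyond which harmonic
#'   walls engage; defaults span the basin centers plus six widths.
#' @param wall_k wall stiffness.
#' @return An object of class `potential_spec`.
#' @export
potential_spec <- function(centers, depths, widths, kT = 1, diffusion = 1,
                           harmonic_k = NULL, gate_coupling = 0,
                           escape_index = 1L, gate_index = NULL, gate_ref = 0,
                           wall_lo = NULL, wall_hi = NULL, wall_k = 10) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 1L)
  centers <- as.matrix(centers)
  n_basins <- nrow(centers)
  ndim <- ncol(centers)
  depths <- as.numeric(depths)
  if (is.null(dim(widths))) {
    if (length(widths) != n_basins)
      stop("widths must have one entry (or row) per basin")
    widths <- matrix(rep(as.numeric(widths), ndim), n_basins, ndim)
  }
  widths <- as.matrix(widths)
  if (n_basins < 1L) stop("at least one basin is required")
  if (length(depths) != n_basins || !all(dim(widths) == c(n_basins, ndim)))
    stop("depths and widths must have one entry (or row) per basin")
  if (any(widths <= 0)) stop("all basin widths must be > 0")
  if (kT <= 0) stop("kT must be > 0")
  if (diffusion < 0) stop("diffusion coefficient must be >= 0")
  if (is.null(harmonic_k)) harmonic_k <- rep(0, ndim)
  if (length(harmonic_k) != ndim) stop("harmonic_k must have one entry per coordinate")
  if (gate_coupling != 0 && is.null(gate_index))
    stop("gate_index is required when gate_coupling != 0")
  if (is.null(gate_index)) gate_index <- NA_integer_
  if (is.null(wall_lo)) wall_lo <- apply(centers, 2, min) - 6 * max(widths)
  if (is.null(wall_hi)) wall_hi <- apply(centers, 2, max) + 6 * max(widths)
  if (any(wall_hi <= wall_lo)) stop("wall_hi must exceed wall_lo")
  spec <- structure(list(
    centers = centers, depths = depths, widths = widths, kT = kT,
    diffusion = diffusion, harmonic_k = as.numeric(harmonic_k),
    gate_coupling = gate_coupling,
    escape_index = as.integer(escape_index),
    gate_index = as.integer(gate_index), gate_ref = gate_ref,
    wall_lo = as.numeric(wall_lo), wall_hi = as.numeric(wall_hi),
    wall_k = wall_k, ndim = ndim
  ), class = "potential_spec")
  for (b in seq_len(n_basins)) {
    u <- potential_energy(spec, centers[b, ])
    if (!is.finite(u)) stop("potential does not evaluate finitely at basin center ", b)
  }
  spec
}

#' @export
print.potential_spec <- function(x, ...) {
  cat(sprintf("potential_spec: %d basin(s) in %d dimension(s), kT = %g, D = %g\n",
              nrow(x$centers), x$ndim, x$kT, x$diffusion))
  if (x$gate_coupling != 0)
    cat(sprintf("  gate coupling g = %g between coordinates %d (escape) and %d (gate)\n",
                x$gate_coupling, x$escape_index, x$gate_index))
  invisible(x)
}

gate_idx0 <- function(spec) {
  if (spec$gate_coupling == 0 || is.na(spec$gate_index)) c(-1L, -1L)
  else c(spec$escape_index - 1L, spec$gate_index - 1L)
}

#' Evaluate the potential energy or gradient
#'
#' @param spec a [potential_spec()].
#' @param x numeric position vector.
#' @return Scalar energy (kT units) or gradient vector.
#' @export
potential_energy <- function(spec, x) {
  idx <- gate_idx0(spec)
  potential_energy_cpp(as.numeric(x), spec$centers, spec$depths, spec$widths,
                       spec$harmonic_k, spec$gate_coupling, idx[1], idx[2],
                       spec$gate_ref, spec$wall_lo, spec$wall_hi, spec$wall_k)
}

#' @rdname potential_energy
#' @export
potential_gradient <- function(spec, x) {
  idx <- gate_idx0(spec)
  potential_gradient_cpp(as.numeric(x), spec$centers, spec$depths, spec$widths,
                         spec$harmonic_k, spec$gate_coupling, idx[1], idx[2],
                         spec$gate_ref, spec$wall_lo, spec$wall_hi, spec$wall_k)
}

#' Construct a trajectory object
#'
#' @param frames numeric matrix, one row per frame, one column per coordinate
#'   (or feature).
#' @param frame_interval time between consecutive frames (> 0).
#' @param seed integer seed the trajectory was generated with (NA for data of
#'   external origin).
#' @param bias_record optional matrix of per-frame bias centers for steered
#'   pulls.
#' @param diverged logical flag set when the simulation left its declared
#'   domain and was truncated.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, frame_interval, seed = NA_integer_,
                       bias_record = NULL, diverged = FALSE) {
  frames <- as.matrix(frames)
  if (nrow(frames) < 2L) stop("a trajectory needs at least 2 frames")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (!all(is.finite(frames))) stop("trajectory frames contain non-finite values")
  structure(list(frames = frames, frame_interval = frame_interval,
                 seed = seed, bias_record = bias_record, diverged = diverged),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d dims, frame interval %g%s%s\n",
              nrow(x$frames), ncol(x$frames), x$frame_interval,
              if (!is.null(x$bias_record)) ", biased (pull)" else "",
              if (isTRUE(x$diverged)) ", TRUNCATED (left domain)" else ""))
  invisible(x)
}

#' Overdamped Langevin (Brownian) dynamics on a potential
#'
#' First-order Euler-Maruyama integration of
#' \deqn{x \leftarrow x - (D/kT)\,\nabla U\,dt + \sqrt{2 D\,dt}\,\xi}
#' with standard-normal \eqn{\xi}. The trajectory is bit-reproducible given
#' `seed`. A step-size guard refuses time steps whose deterministic drift at
#' the start position exceeds a tenth of the narrowest basin width; a
#' trajectory that leaves the walled domain by a wide margin is truncated and
#' flagged rather than propagated into overflow.
#'
#' @inheritParams potential_energy
#' @param n_steps number of integration steps.
#' @param dt time step.
#' @param seed integer RNG seed.
#' @param start numeric start position.
#' @param save_every keep every `save_every`-th frame (frame 0 always kept),
#'   so the returned `frame_interval` is `dt * save_every`.
#' @return A [trajectory()].
#' @export
simulate_langevin <- function(spec, n_steps, dt, seed, start, save_every = 1L) {
  stopifnot(inherits(spec, "potential_spec"))
  start <- as.numeric(start)
  if (length(start) != spec$ndim) stop("start has wrong dimensionality")
  if (n_steps < 1L) stop("n_steps must be >= 1")
  g0 <- potential_gradient(spec, start)
  if (!all(is.finite(g0))) stop("non-finite potential gradient at start position")
  drift <- spec$diffusion / spec$kT * max(abs(g0)) * dt
  if (drift > min(spec$widths) / 10)
    stop(sprintf(paste0("time step too large: deterministic displacement per step ",
                        "%.3g exceeds width/10 = %.3g at the start position"),
                 drift, min(spec$widths) / 10))
  idx <- gate_idx0(spec)
  domain_limit <- max(abs(c(spec$wall_lo, spec$wall_hi))) + 20 * max(spec$widths)
  set.seed(seed)
  res <- langevin_cpp(start, as.integer(n_steps), dt, spec$diffusion, spec$kT,
                      as.integer(save_every), spec$centers, spec$depths,
                      spec$widths, spec$harmonic_k, spec$gate_coupling,
                      idx[1], idx[2], spec$gate_ref, spec$wall_lo, spec$wall_hi,
                      spec$wall_k, FALSE, numeric(spec$ndim),
                      numeric(spec$ndim), numeric(spec$ndim), 0, domain_limit)
  if (isTRUE(res$diverged))
    warning("trajectory left the declared domain and was truncated")
  trajectory(res$frames, dt * save_every, seed = as.integer(seed),
             diverged = isTRUE(res$diverged))
}

#' Define a steered-pull protocol
#'
#' A moving harmonic restraint \eqn{\tfrac12 k (x - c(t))^2} with
#' \eqn{c(t) = c_0 + v\,t\,\hat{u}} dragging the system along a direction, as
#' in steered (pulling) molecular dynamics. Defaults mirror the common
#' protocol of a 10 energy/length^2 spring moved at 0.01 length/time.
#'
#' @param direction pull direction; normalized to a unit vector.
#' @param spring_constant restraint stiffness k (> 0).
#' @param pull_rate speed v of the restraint center (> 0).
#' @param duration total pull time; used by [simulate_steered_pull()] to set
#'   the default number of steps.
#' @param restrained_coordinates indices of coordinates held (with the same
#'   spring) at their starting values during the pull.
#' @return An object of class `pull_spec`.
#' @export
pull_spec <- function(direction, spring_constant = 10, pull_rate = 0.01,
                      duration = NULL, restrained_coordinates = integer(0)) {
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a nonzero vector")
  if (spring_constant <= 0) stop("spring_constant must be > 0")
  if (pull_rate <= 0) stop("pull_rate must be > 0")
  structure(list(direction = direction / nrm, spring_constant = spring_constant,
                 pull_rate = pull_rate, duration = duration,
                 restrained_coordinates = as.integer(restrained_coordinates)),
            class = "pull_spec")
}

#' Steered-pull Langevin simulation
#'
#' [simulate_langevin()] plus the moving harmonic bias of a [pull_spec()].
#' The per-frame bias center is recorded in the returned trajectory's
#' `bias_record`.
#'
#' @inheritParams simulate_langevin
#' @param pull a [pull_spec()].
#' @param n_steps number of steps; defaults to `pull$duration / dt` when the
#'   pull declares a duration.
#' @export
simulate_steered_pull <- function(spec, pull, n_steps = NULL, dt, seed, start,
                                  save_every = 1L) {
  stopifnot(inherits(spec, "potential_spec"), inherits(pull, "pull_spec"))
  start <- as.numeric(start)
  if (length(start) != spec$ndim) stop("start has wrong dimensionality")
  if (length(pull$direction) != spec$ndim)
    stop("pull direction has wrong dimensionality")
  if (is.null(n_steps)) {
    if (is.null(pull$duration)) stop("either n_steps or pull$duration is required")
    n_steps <- ceiling(pull$duration / dt)
  }
  bias_k <- numeric(spec$ndim)
  bias_k[pull$direction != 0] <- pull$spring_constant
  bias_k[pull$restrained_coordinates] <- pull$spring_constant
  idx <- gate_idx0(spec)
  domain_limit <- max(abs(c(spec$wall_lo, spec$wall_hi))) + 20 * max(spec$widths)
  set.seed(seed)
  res <- langevin_cpp(start, as.integer(n_steps), dt, spec$diffusion, spec$kT,
                      as.integer(save_every), spec$centers, spec$depths,
                      spec$widths, spec$harmonic_k, spec$gate_coupling,
                      idx[1], idx[2], spec$gate_ref, spec$wall_lo, spec$wall_hi,
                      spec$wall_k, TRUE, bias_k, start, pull$direction,
                      pull$pull_rate, domain_limit)
  if (isTRUE(res$diverged))
    warning("trajectory left the declared domain and was truncated")
  trajectory(res$frames, dt * save_every, seed = as.integer(seed),
             bias_record = res$bias, diverged = isTRUE(res$diverged))
}

#' Adaptive seeding: cluster pull frames, sample starts per cluster
#'
#' Pools the frames of biased pull trajectories, groups them with K-center
#' clustering, and draws a few start positions uniformly from each cluster —
#' the standard seeding scheme for launching many short unbiased runs along a
#' pulled pathway (20 clusters and 3–5 picks each yield ~100 seeds).
#'
#' @param pull_trajectories list of [trajectory()] objects.
#' @param n_clusters number of K-center clusters (default 20).
#' @param picks_per_cluster integer vector of admissible picks per cluster;
#'   each cluster contributes `sample(picks_per_cluster, 1)` starts (default
#'   3–5). Clusters smaller than the drawn count contribute all their frames,
#'   with a warning.
#' @param metric optional [metric_spec()] under which frames are compared;
#'   default plain Euclidean distance.
#' @param seed integer seed controlling both the cluster pick counts and the
#'   within-cluster sampling.
#' @return Matrix of start positions (one row each) with attribute `cluster`
#'   giving each start's source cluster.
#' @export
adaptive_seed <- function(pull_trajectories, n_clusters = 20L,
                          picks_per_cluster = 3:5, metric = NULL, seed = 1L) {
  if (length(pull_trajectories) == 0L) stop("pull_trajectories must be nonempty")
  pool <- do.call(rbind, lapply(pull_trajectories, function(tr) tr$frames))
  if (n_clusters > nrow(pool)) stop("n_clusters exceeds the number of pooled frames")
  km <- kcenter(pool, k = n_clusters, metric = metric, seed = seed)
  set.seed(derive_seed(seed, 1L))
  starts <- list(); clus <- integer(0)
  for (cl in seq_len(n_clusters)) {
    members <- which(km$assignments == cl)
    want <- if (length(picks_per_cluster) > 1L)
      sample(picks_per_cluster, 1L) else picks_per_cluster
    if (length(members) < want) {
      warning(sprintf("cluster %d has only %d frame(s); taking all of them",
                      cl, length(members)))
      take <- members
    } else {
      take <- members[sample.int(length(members), want)]
    }
    starts[[cl]] <- pool[take, , drop = FALSE]
    clus <- c(clus, rep(cl, length(take)))
  }
  out <- do.call(rbind, starts)
  rownames(out) <- NULL
  attr(out, "cluster") <- clus
  out
}

#' Define an exact discrete Markov chain
#'
#' @param transition_matrix square row-stochastic matrix (rows must sum to 1
#'   within 1e-9; they are renormalized exactly on construction).
#' @param state_labels optional state names.
#' @param lag_unit physical time per chain step (label only).
#' @return An object of class `discrete_chain_spec`.
#' @export
discrete_chain_spec <- function(transition_matrix, state_labels = NULL,
                                lag_unit = 1) {
  T <- as.matrix(transition_matrix)
  if (nrow(T) != ncol(T)) stop("transition matrix must be square")
  if (any(T < 0)) stop("transition probabilities must be non-negative")
  rs <- rowSums(T)
  if (any(abs(rs - 1) > 1e-9))
    stop("rows of the transition matrix must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  T <- T / rs
  structure(list(transition_matrix = T,
                 state_labels = state_labels %||% as.character(seq_len(nrow(T))),
                 lag_unit = lag_unit),
            class = "discrete_chain_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a discrete Markov chain
#'
#' @param spec a [discrete_chain_spec()] or a row-stochastic matrix.
#' @param n_steps number of transitions to draw.
#' @param seed integer RNG seed.
#' @param start_state 1-based starting state.
#' @return Integer vector of `n_steps + 1` states (the start included).
#' @export
sample_discrete_chain <- function(spec, n_steps, seed, start_state = 1L) {
  if (!inherits(spec, "discrete_chain_spec")) spec <- discrete_chain_spec(spec)
  T <- spec$transition_matrix
  n <- nrow(T)
  if (start_state < 1L || start_state > n) stop("start_state out of range")
  set.seed(seed)
  sample_chain_cpp(T, as.integer(n_steps), as.integer(start_state) - 1L)
}
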