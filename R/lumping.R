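# PCCA+ coarse-graining of microstates into metastable macrostates:
# inner-simplex (vertex) initialization on the dominant eigenvector basis,
# feasibility projection, and crispness refinement by a local optimizer.

#' PCCA+ lumping of a Markov model
#'
#' Builds the invariant-subspace basis from the top `n_macro` eigenvectors of
#' the (symmetrized) transition matrix, locates the simplex vertices by the
#' inner-simplex index search (farthest-point rows of the eigenvector
#' matrix), projects the resulting linear map back into the feasible set, and
#' refines it by maximizing the crispness criterion
#' \eqn{\mathrm{tr}(D^{-1} A^\top A)} with a local optimizer. Ties in vertex
#' selection break to the lowest row index.
#'
#' For a non-reversible transition matrix the spectral basis is taken from
#' the pi-symmetrized matrix, with a warning.
#'
#' @param model a `markov_model` (irreducible by construction).
#' @param n_macro number of macrostates (`1 <= n_macro <= n_micro`).
#' @param refine run the local optimizer after vertex initialization
#'   (default TRUE; with `n_macro = 1` or identity lumping it is a no-op).
#' @param state_names optional macrostate names; default `M1, M2, ...` in
#'   decreasing-population order.
#' @return An object of class `macrostate_model` with fields `n_macro`,
#'   `membership` (fuzzy chi, rows sum to 1), `crisp_map` (micro -> macro),
#'   `macro_populations` (pi-mass of crisp members), `state_names`, and
#'   `micro_stationary`.
#' @export
pcca_plus <- function(model, n_macro, refine = TRUE, state_names = NULL) {
  Tm <- model$transition_matrix
  pi <- model$stationary
  n <- nrow(Tm)
  m <- as.integer(n_macro)
  if (m < 1L || m > n) stop("n_macro must be between 1 and the number of microstates")
  if (m == 1L) {
    chi <- matrix(1, n, 1)
    return(new_macrostate_model(chi, rep(1L, n), pi, state_names %||% "M1"))
  }
  if (m == n) {
    chi <- diag(n)
    return(new_macrostate_model(chi, seq_len(n), pi,
                                state_names %||% paste0("M", seq_len(n))))
  }
  sp <- sqrt(pi)
  S <- diag(sp) %*% Tm %*% diag(1 / sp)
  asym <- max(abs(S - t(S))) / max(abs(S))
  if (asym > 1e-8)
    warning(sprintf(paste0("transition matrix is not reversible (relative ",
                           "asymmetry %.2g); operating on the symmetrized matrix"),
                    asym))
  Ssym <- (S + t(S)) / 2
  ev <- eigen(Ssym, symmetric = TRUE)
  mu <- ev$values
  if (abs(mu[m] - mu[m + 1]) < 1e-3)
    warning(sprintf("small spectral gap after mode %d: |mu_%d - mu_%d| = %.2g",
                    m, m, m + 1, abs(mu[m] - mu[m + 1])))
  psi <- ev$vectors[, seq_len(m), drop = FALSE] / sp  # pi-orthonormal basis
  psi[, 1] <- 1  # leading eigenvector is constant up to scale/sign
  idx <- isa_index_search(psi)
  A <- solve(psi[idx, , drop = FALSE])
  A <- pcca_fill_A(A, psi)
  if (refine && m > 1L) {
    free0 <- as.numeric(A[2:m, 2:m])
    obj <- function(v) {
      Af <- A
      Af[2:m, 2:m] <- matrix(v, m - 1L, m - 1L)
      Af <- pcca_fill_A(Af, psi)
      -sum(diag(crossprod(Af) %*% diag(1 / Af[1, ], m)))
    }
    opt <- stats::optim(free0, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    if (opt$value <= obj(free0)) {
      A[2:m, 2:m] <- matrix(opt$par, m - 1L, m - 1L)
      A <- pcca_fill_A(A, psi)
    }
  }
  chi <- psi %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  crisp <- max.col(chi, ties.method = "first")
  new_macrostate_model(chi, crisp, pi, state_names)
}

# Inner-simplex vertex search: iteratively pick the row farthest from the
# span of the vertices found so far (Gram-Schmidt deflation). Ties break to
# the lowest row index via which.max.
isa_index_search <- function(psi) {
  m <- ncol(psi)
  ortho <- psi
  idx <- integer(m)
  for (j in seq_len(m)) {
    norms <- sqrt(rowSums(ortho^2))
    idx[j] <- which.max(norms)
    v <- ortho[idx[j], ] / norms[idx[j]]
    ortho <- ortho - outer(as.numeric(ortho %*% v), v)
  }
  idx
}

# Feasibility projection of the simplex transform (Roeblitz-Weber): the free
# block A[2:m, 2:m] determines the rest so that chi = psi %*% A is
# non-negative with unit row sums.
pcca_fill_A <- function(A, psi) {
  m <- ncol(A)
  if (m == 1L) return(matrix(1 / psi[1, 1]))
  A[2:m, 1] <- -rowSums(A[2:m, 2:m, drop = FALSE])
  rest <- psi[, 2:m, drop = FALSE] %*% A[2:m, , drop = FALSE]
  A[1, ] <- -apply(rest, 2, min)
  A / sum(A[1, ])
}

new_macrostate_model <- function(chi, crisp, pi, state_names = NULL) {
  m <- ncol(chi)
  pops <- vapply(seq_len(m), function(j) sum(pi[crisp == j]), 0)
  # stable naming: macrostates reported in decreasing-population order
  ord <- order(pops, decreasing = TRUE)
  relabel <- match(seq_len(m), ord)
  chi <- chi[, ord, drop = FALSE]
  crisp <- relabel[crisp]
  pops <- pops[ord]
  names <- state_names %||% paste0("M", seq_len(m))
  if (length(names) != m) stop("state_names must have one entry per macrostate")
  structure(list(n_macro = m, membership = chi, crisp_map = as.integer(crisp),
                 macro_populations = pops, state_names = names,
                 micro_stationary = pi),
            class = "macrostate_model")
}

#' @export
print.macrostate_model <- function(x, ...) {
  cat(sprintf("macrostate_model: %d macrostates over %d microstates\n",
              x$n_macro, nrow(x$membership)))
  for (j in seq_len(x$n_macro))
    cat(sprintf("  %s: population %.3f (%d microstates)\n", x$state_names[j],
                x$macro_populations[j], sum(x$crisp_map == j)))
  invisible(x)
}

#' Map microstate label sequences to macrostate labels
#'
#' @param assignments integer microstate labels (vector or list of vectors),
#'   indexed into the lumped model's microstates.
#' @param model a `macrostate_model`.
#' @return Macrostate labels with the same shape as `assignments`.
#' @export
macro_labels <- function(assignments, model) {
  map1 <- function(a) {
    if (any(a < 1L | a > length(model$crisp_map)))
      stop("assignment label outside the microstate range")
    model$crisp_map[a]
  }
  if (is.list(assignments)) lapply(assignments, map1) else map1(assignments)
}

#' Coarse-grain a Markov model onto macrostates
#'
#' Stationary-weighted aggregation:
#' \eqn{T_{IJ} = \sum_{i \in I}\sum_{j \in J} \pi_i T_{ij} / \sum_{i \in I} \pi_i}.
#' The result is the macrostate-level transition matrix consistent with the
#' crisp lumping; it is exact when the lumping respects the dynamics.
#'
#' @param model a `markov_model` over microstates.
#' @param lumping a `macrostate_model` (or an integer crisp map).
#' @return A `markov_model` over the macrostates, at the same lag.
#' @export
coarse_grain <- function(model, lumping) {
  crisp <- if (inherits(lumping, "macrostate_model")) lumping$crisp_map else as.integer(lumping)
  Tm <- model$transition_matrix
  pi <- model$stationary
  m <- max(crisp)
  M <- matrix(0, m, m)
  for (I in seq_len(m)) {
    wi <- pi[crisp == I]
    M[I, ] <- vapply(seq_len(m), function(J) {
      sum(wi * rowSums(Tm[crisp == I, crisp == J, drop = FALSE])) / sum(wi)
    }, 0)
  }
  Cmac <- t(rowsum(t(rowsum(model$count_matrix, crisp)), crisp))
  mu <- eigen(M)$values
  structure(list(
    lag = model$lag, lag_time = model$lag_time,
    count_matrix = Cmac,
    transition_matrix = M,
    eigenvalues = mu[order(Mod(mu), decreasing = TRUE)],
    stationary = as.numeric(vapply(seq_len(m), function(I) sum(pi[crisp == I]), 0)),
    active_set = seq_len(m),
    n_discarded_counts = 0,
    reversible = model$reversible
  ), class = "markov_model")
}
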