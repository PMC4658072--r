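# Markov state model estimation and validation: sliding-window transition
# counts, connectivity-restricted transition matrices, propagation, implied
# timescales, and the Chapman-Kolmogorov self-transition test.

#' Count lagged transitions in label sequences
#'
#' Sliding-window counting: for every frame `t` with `t + lag` in range,
#' `C[s(t), s(t + lag)]` is incremented. Windows never cross trajectory
#' boundaries. Sequences too short for the lag are skipped with a warning.
#'
#' @param sequences list of integer label vectors (labels in `1..n_states`),
#'   or a single vector.
#' @param lag lag in frames (>= 1).
#' @param n_states matrix dimension; defaults to the largest label seen.
#' @return `n_states x n_states` integer count matrix.
#' @export
count_transitions <- function(sequences, lag, n_states = NULL) {
  if (!is.list(sequences)) sequences <- list(sequences)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1")
  if (is.null(n_states)) n_states <- max(vapply(sequences, max, 0L))
  n <- as.integer(n_states)
  usable <- vapply(sequences, length, 0L) > lag
  if (!any(usable)) stop("all sequences are shorter than the lag")
  if (!all(usable)) warning(sum(!usable), " sequence(s) shorter than the lag skipped")
  C <- matrix(0, n, n)
  for (s in sequences[usable]) {
    L <- length(s)
    from <- s[seq_len(L - lag)]
    to <- s[(lag + 1L):L]
    C <- C + matrix(tabulate((to - 1L) * n + from, nbins = n * n), n, n)
  }
  C
}

# Largest strongly connected component of the count graph (edges with
# count >= 1), via Tarjan's algorithm as implemented in igraph.
largest_scc <- function(C) {
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership)
  keep <- which(comp$membership == which.max(sizes))
  sort(keep)
}

#' Estimate a Markov model from a transition count matrix
#'
#' Restricts the counts to the largest strongly connected component of the
#' count graph, row-normalizes (default, non-reversible), or optionally
#' applies the reversible maximum-likelihood estimator (iterative
#' symmetrization), then computes the spectrum and the stationary
#' distribution as the leading left eigenvector.
#'
#' @param count_matrix non-negative square count matrix.
#' @param lag lag (in frames) the counts were taken at.
#' @param lag_time physical duration of one lag step (label used for
#'   reporting; default `lag`).
#' @param reversible if TRUE, use the reversible maximum-likelihood
#'   symmetrization instead of plain row normalization.
#' @return An object of class `markov_model` with fields `lag`, `lag_time`,
#'   `count_matrix` (restricted), `transition_matrix`, `eigenvalues` (sorted
#'   by modulus, leading first), `stationary`, `active_set` (original state
#'   indices retained), and `n_discarded_counts`.
#' @export
estimate_markov_model <- function(count_matrix, lag = 1L, lag_time = NULL,
                                  reversible = FALSE) {
  C <- as.matrix(count_matrix)
  if (any(C < 0)) stop("count matrix must be non-negative")
  if (nrow(C) != ncol(C)) stop("count matrix must be square")
  active <- largest_scc(C)
  if (length(active) == 0L) stop("count graph has no connected component")
  Cr <- C[active, active, drop = FALSE]
  rs <- rowSums(Cr)
  stopifnot(all(rs > 0))  # impossible inside an SCC by construction
  if (reversible) {
    T <- reversible_mle(Cr)
  } else {
    T <- Cr / rs
  }
  eig <- eigen(T)
  ord <- order(Mod(eig$values), decreasing = TRUE)
  mu <- eig$values[ord]
  pi <- stationary_distribution(T)
  structure(list(
    lag = as.integer(lag),
    lag_time = lag_time %||% as.numeric(lag),
    count_matrix = Cr,
    transition_matrix = T,
    eigenvalues = mu,
    stationary = pi,
    active_set = active,
    n_discarded_counts = sum(C) - sum(Cr),
    reversible = reversible
  ), class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("markov_model: %d states at lag %d (lag time %g), %s estimator\n",
              nrow(x$transition_matrix), x$lag, x$lag_time,
              if (x$reversible) "reversible" else "row-normalized"))
  cat(sprintf("  slowest nontrivial eigenvalue: %.6g\n", Mod(x$eigenvalues[2])))
  invisible(x)
}

# Reversible maximum-likelihood estimator via the standard fixed-point
# iteration on x_ij = (c_ij + c_ji) / (c_i/x_i + c_j/x_j).
reversible_mle <- function(C, tol = 1e-12, max_iter = 5000L) {
  Cs <- C + t(C)
  X <- Cs / sum(Cs)
  ci <- rowSums(C)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, `+`)
    Xn <- Cs / denom
    Xn[Cs == 0] <- 0
    Xn <- Xn / sum(Xn)
    if (max(abs(Xn - X)) < tol) { X <- Xn; break }
    X <- Xn
  }
  X / rowSums(X)
}

# Stationary distribution: leading left eigenvector, made real and
# normalized to sum 1.
stationary_distribution <- function(T) {
  e <- eigen(t(T))
  i <- which.min(Mod(e$values - 1))
  v <- Re(e$vectors[, i])
  if (sum(v) < 0) v <- -v
  v[v < 0 & v > -1e-12] <- 0
  v / sum(v)
}

#' Propagate a population vector
#'
#' Advances `P0` by `n` lag steps: `P(n dt) = P0 %*% T^n` (populations as a
#' row vector acting on the row-stochastic matrix). Matrix powers are taken
#' by repeated squaring.
#'
#' @param model a `markov_model`.
#' @param P0 initial population vector over the active states (non-negative,
#'   sums to 1).
#' @param n number of lag steps (>= 0).
#' @return The propagated population vector.
#' @export
propagate <- function(model, P0, n) {
  T <- model$transition_matrix
  P0 <- as.numeric(P0)
  if (length(P0) != nrow(T)) stop("P0 dimension does not match the active state set")
  if (any(P0 < 0) || abs(sum(P0) - 1) > 1e-8) stop("P0 must be a probability vector")
  if (n == 0L) return(P0)
  as.numeric(P0 %*% matpow(T, n))
}

matpow <- function(M, n) {
  n <- as.integer(n)
  R <- diag(nrow(M))
  B <- M
  while (n > 0L) {
    if (n %% 2L == 1L) R <- R %*% B
    n <- n %/% 2L
    if (n > 0L) B <- B %*% B
  }
  R
}

#' Implied timescales of a transition matrix
#'
#' \eqn{\tau_k = -\tau / \ln \mu_k(\tau)} for the top nontrivial eigenvalues.
#' Non-positive eigenvalues give no defined timescale and are flagged, not
#' dropped; eigenvalues at 1 (reducible dynamics) give an infinite timescale;
#' complex pairs (possible for non-reversible estimates) are reported by
#' modulus with a flag.
#'
#' @param mu eigenvalue vector sorted by modulus (leading 1 first), as stored
#'   in a `markov_model`.
#' @param lag_time physical lag time tau.
#' @param k_modes number of nontrivial modes to report.
#' @return data.frame with columns `k`, `mu` (modulus), `tau`, `flag`.
#' @export
timescales_from_eigenvalues <- function(mu, lag_time, k_modes) {
  k_modes <- min(k_modes, length(mu) - 1L)
  out <- data.frame(k = integer(0), mu = numeric(0), tau = numeric(0),
                    flag = character(0), stringsAsFactors = FALSE)
  for (k in seq_len(k_modes)) {
    m <- mu[k + 1L]
    flag <- "ok"
    if (abs(Im(m)) > 1e-12) flag <- "complex"
    mm <- if (flag == "complex") Mod(m) else Re(m)
    if (mm >= 1 - 1e-12) {
      tau <- Inf; flag <- "unit"
    } else if (mm <= 0) {
      tau <- NA_real_; flag <- "nonpositive"
    } else {
      tau <- -lag_time / log(mm)
    }
    out <- rbind(out, data.frame(k = k, mu = mm, tau = tau, flag = flag,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Implied-timescale curve across lag times
#'
#' Builds a Markov model at each lag and reports \eqn{\tau_k = -\tau/\ln\mu_k}
#' for the top `k_modes` nontrivial eigenvalues. A flat curve across lags is
#' the standard indicator that the model has become markovian.
#'
#' @inheritParams count_transitions
#' @param lags strictly increasing integer lags (frames).
#' @param k_modes number of nontrivial modes per lag.
#' @param frame_interval physical time per frame (so the lag time is
#'   `lag * frame_interval`).
#' @param reversible passed to [estimate_markov_model()].
#' @return data.frame of class `timescale_curve` with columns `lag`,
#'   `lag_time`, `k`, `mu`, `tau`, `flag`.
#' @export
implied_timescales <- function(sequences, lags, k_modes = 3L,
                               frame_interval = 1, n_states = NULL,
                               reversible = FALSE) {
  if (is.unsorted(lags, strictly = TRUE)) stop("lags must be strictly increasing")
  if (!is.list(sequences)) sequences <- list(sequences)
  if (max(lags) >= max(vapply(sequences, length, 0L)))
    stop("largest lag is not smaller than the longest sequence")
  rows <- lapply(lags, function(lag) {
    C <- count_transitions(sequences, lag, n_states = n_states)
    m <- estimate_markov_model(C, lag = lag, lag_time = lag * frame_interval,
                               reversible = reversible)
    ts <- timescales_from_eigenvalues(m$eigenvalues, m$lag_time, k_modes)
    cbind(data.frame(lag = lag, lag_time = lag * frame_interval), ts)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("timescale_curve", class(out))
  out
}

#' Chapman-Kolmogorov self-transition test
#'
#' For selected states and lag multiples `n`, compares the model prediction
#' `[T^n]_ii` against the self-transition probability counted directly from
#' the data at lag `n * tau`, with a binomial standard error. By default the
#' most populated states (by empirical visit counts) are tested.
#'
#' @inheritParams count_transitions
#' @param model a `markov_model` built from these sequences at its lag.
#' @param multiples integer lag multiples (n = 1 is predicted = observed by
#'   construction).
#' @param states states to test, as indices into the model's active set;
#'   default the `n_states_tested` most populated.
#' @param n_states_tested how many top-population states to select when
#'   `states` is NULL (default 6).
#' @return data.frame of class `ck_report` with columns `state` (original
#'   label), `n`, `predicted`, `observed`, `se`, `n_windows`, `missing`.
#' @export
chapman_kolmogorov <- function(sequences, model, multiples = 1:5,
                               states = NULL, n_states_tested = 6L) {
  if (!is.list(sequences)) sequences <- list(sequences)
  T <- model$transition_matrix
  active <- model$active_set
  if (is.null(states)) {
    counts <- rowSums(model$count_matrix)
    states <- order(counts, decreasing = TRUE)[seq_len(min(n_states_tested, nrow(T)))]
  }
  n_all <- max(vapply(sequences, max, 0L), max(active))
  out <- list()
  for (n in sort(unique(as.integer(multiples)))) {
    Tn <- matpow(T, n)
    Cn <- count_transitions(sequences, n * model$lag, n_states = n_all)
    Cn <- Cn[active, active, drop = FALSE]
    for (s in states) {
      tot <- sum(Cn[s, ])
      if (tot == 0) {
        out[[length(out) + 1L]] <- data.frame(
          state = active[s], n = n, predicted = Tn[s, s],
          observed = NA_real_, se = NA_real_, n_windows = 0L, missing = TRUE)
      } else {
        p <- Cn[s, s] / tot
        out[[length(out) + 1L]] <- data.frame(
          state = active[s], n = n, predicted = Tn[s, s], observed = p,
          se = sqrt(max(p * (1 - p), 1 / tot^2) / tot),
          n_windows = tot, missing = FALSE)
      }
    }
  }
  rep <- do.call(rbind, out)
  class(rep) <- c("ck_report", class(rep))
  rep
}
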