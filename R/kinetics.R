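# Mean first passage times three ways: exact linear solve on the transition
# matrix, Monte-Carlo first-passage sampling with truncated log-count
# (Poisson) regression averaged over replicas, and the stationary-weighted
# upper bound from untruncated microstate MFPTs.

#' Mean first passage time by linear solve
#'
#' Solves the first-passage system \eqn{f_i = \sum_k P_{ik}(\tau + f_k)} for
#' states outside the target with the boundary condition \eqn{f_j = 0} on the
#' target, then returns the stationary-weighted average of \eqn{f_i} over the
#' source states (weights restricted and renormalized to the source set).
#' An unreachable target yields `Inf` with a warning.
#'
#' @param model a `markov_model`.
#' @param source,target non-overlapping state index sets (positions in the
#'   model's active set).
#' @param full also return the full vector of per-state MFPTs as attribute
#'   `"f"`.
#' @return MFPT in the model's `lag_time` units (0 when source is inside the
#'   target set).
#' @export
mfpt_solve <- function(model, source, target, full = FALSE) {
  Tm <- model$transition_matrix
  n <- nrow(Tm)
  source <- as.integer(source); target <- as.integer(target)
  if (length(target) == 0L) stop("target set must be nonempty")
  if (any(c(source, target) < 1L) || any(c(source, target) > n))
    stop("state indices out of range")
  f <- mfpt_vector(Tm, target, model$lag_time)
  if (any(!is.finite(f[source]))) {
    warning("target is not reachable from (part of) the source; MFPT is infinite")
    return(Inf)
  }
  w <- model$stationary[source]
  val <- sum(w * f[source]) / sum(w)
  if (full) attr(val, "f") <- f
  val
}

# Per-state MFPTs to a target set: (I - P_BB) f_B = tau * 1 on the
# complement B of the target. States that cannot reach the target at all
# come back as Inf.
mfpt_vector <- function(Tm, target, tau) {
  n <- nrow(Tm)
  B <- setdiff(seq_len(n), target)
  f <- numeric(n)
  if (length(B) == 0L) return(f)
  # reachability check on the count graph restricted to B
  reach <- rep(FALSE, n)
  reach[target] <- TRUE
  repeat {
    newly <- which(!reach & (Tm %*% reach > 0))
    if (length(newly) == 0L) break
    reach[newly] <- TRUE
  }
  if (!all(reach)) {
    f[!reach] <- Inf
    B <- B[reach[B]]
    if (length(B) == 0L) return(f)
  }
  A <- diag(length(B)) - Tm[B, B, drop = FALSE]
  f[B] <- solve(A, rep(tau, length(B)))
  f
}

#' Collect first-passage events from a macrostate label sequence
#'
#' Event convention: a passage opens at each entry into the source set from a
#' non-source state (and at the first frame if the sequence starts in the
#' source) and closes at the first subsequent visit to the target set.
#' Re-entering the source while a passage is open does not reset it, open
#' passages never overlap, and a passage unfinished at the end of the
#' sequence is discarded.
#'
#' @param labels integer (or factor/character) state sequence.
#' @param source,target disjoint label sets.
#' @param tau time per sequence step (default 1 lag unit).
#' @param replica_id identifier carried into the sample.
#' @return An object of class `fpt_sample`: list with `times` (passage
#'   durations, in `tau` units), `source`, `target`, `tau`, `replica_id`.
#' @export
collect_first_passages <- function(labels, source, target, tau = 1,
                                   replica_id = 1L) {
  if (length(intersect(source, target)) > 0L)
    stop("source and target sets must be disjoint")
  in_s <- labels %in% source
  in_t <- labels %in% target
  L <- length(labels)
  entries <- which(in_s & c(TRUE, !in_s[-L]))
  hits <- which(in_t)
  # each entry completes at the first target visit after it; entries sharing
  # that completion lie inside one open passage, so only the earliest one in
  # each inter-hit gap opens a passage (no double counting, no reset).
  if (length(entries) > 0L && length(hits) > 0L) {
    g <- findInterval(entries, hits) + 1L   # index of the completing hit
    done <- g <= length(hits)               # unfinished at sequence end: drop
    g <- g[done]
    e <- entries[done]
    first <- !duplicated(g)
    times <- (hits[g[first]] - e[first]) * tau
  } else {
    times <- numeric(0)
  }
  structure(list(times = times, source = source, target = target, tau = tau,
                 replica_id = replica_id),
            class = "fpt_sample")
}

#' @export
print.fpt_sample <- function(x, ...) {
  cat(sprintf("fpt_sample: %d passages (replica %s), mean %.4g\n",
              length(x$times), format(x$replica_id),
              if (length(x$times)) mean(x$times) else NA))
  invisible(x)
}

#' Exponential mean from a truncated log-count regression
#'
#' Histograms the passage times, then fits `ln(count)` against time by least
#' squares over a truncation window that discards the fastest and slowest
#' passages, as appropriate for a Poisson-count histogram of an exponential
#' first-passage distribution. The fitted mean is `-1/slope`. The default
#' window spans the central [5%, 95%] quantiles; with `refine_window = TRUE`
#' a small grid of candidate windows is scanned and the window with the best
#' r-squared (with at least 5 occupied bins) is used.
#'
#' @param sample an `fpt_sample` (or a numeric vector of passage times).
#' @param bin_width histogram bin width; default Freedman-Diaconis with a
#'   floor of one lag unit.
#' @param window quantile pair for truncation, default `c(0.05, 0.95)`.
#' @param refine_window scan a small window grid for the best fit.
#' @param min_events minimum number of passage events (default 50).
#' @return An object of class `fpt_fit`: list with `mean`, `slope`, `r2`,
#'   `window` (time units), `bin_width`, `n_events`, `arithmetic_mean`.
#' @export
fit_fpt_poisson <- function(sample, bin_width = NULL, window = c(0.05, 0.95),
                            refine_window = TRUE, min_events = 50L) {
  times <- if (inherits(sample, "fpt_sample")) sample$times else as.numeric(sample)
  tau <- if (inherits(sample, "fpt_sample")) sample$tau else 1
  if (length(times) < min_events)
    stop(sprintf("too few passage events (%d < %d)", length(times), min_events))
  if (diff(range(times)) == 0)
    stop("degenerate passage-time histogram: all passage times identical")
  if (is.null(bin_width)) {
    fd <- 2 * stats::IQR(times) / length(times)^(1 / 3)
    bin_width <- max(fd, tau)
  }
  breaks <- seq(min(times), max(times) + bin_width, by = bin_width)
  h <- graphics::hist(times, breaks = breaks, plot = FALSE, right = FALSE)
  centers <- h$mids
  counts <- h$counts
  fit_in_window <- function(lo, hi) {
    keep <- counts > 0 & centers >= lo & centers <= hi
    if (sum(keep) < 5L) return(NULL)
    fit <- stats::lm(log(counts[keep]) ~ centers[keep])
    s <- stats::coef(fit)[2]
    list(slope = unname(s), r2 = summary(fit)$r.squared,
         window = c(lo, hi), n_bins = sum(keep))
  }
  qs <- stats::quantile(times, window, names = FALSE)
  best <- fit_in_window(qs[1], qs[2])
  if (refine_window) {
    for (lo_q in c(0, 0.025, 0.05, 0.10)) for (hi_q in c(0.90, 0.95, 0.975, 1)) {
      q2 <- stats::quantile(times, c(lo_q, hi_q), names = FALSE)
      cand <- fit_in_window(q2[1], q2[2])
      if (!is.null(cand) && (is.null(best) || cand$r2 > best$r2)) best <- cand
    }
  }
  if (is.null(best))
    stop("too few occupied histogram bins for a regression; widen the bins")
  if (best$slope >= 0)
    stop("log-count regression has a non-negative slope (no exponential decay)")
  structure(list(mean = -1 / best$slope, slope = best$slope, r2 = best$r2,
                 window = best$window, bin_width = bin_width,
                 n_events = length(times), arithmetic_mean = mean(times)),
            class = "fpt_fit")
}

#' Monte-Carlo MFPT with replica-averaged regression estimates
#'
#' Generates `n_replicas` long Monte-Carlo trajectories of the microstate
#' chain, maps them to macrostates through the crisp lumping, collects
#' first-passage events for the requested macro transition, fits each
#' replica's passage-time histogram by [fit_fpt_poisson()], and reports the
#' replica mean with the standard error of the replica means. Replicas whose
#' regression is degenerate fall back to the arithmetic passage mean (with a
#' flag); replicas with no events are dropped with a warning.
#'
#' @param model a `markov_model` over microstates.
#' @param lumping a `macrostate_model` or crisp map vector.
#' @param source,target macrostate labels of the transition.
#' @param n_replicas number of Monte-Carlo replicas (>= 2; default 10).
#' @param steps_per_replica chain steps per replica.
#' @param seed master seed; replica r uses a derived stream.
#' @param ... passed to [fit_fpt_poisson()].
#' @return An object of class `mfpt_estimate`: list with `replica_means`,
#'   `replica_average`, `standard_error`, `n_events`, `regression_r2` (mean
#'   over replicas), `fallback` flags, and the per-replica fits.
#' @export
mfpt_mc <- function(model, lumping, source, target, n_replicas = 10L,
                    steps_per_replica = 1e6, seed = 1L, ...) {
  if (n_replicas < 2L) stop("at least 2 replicas are required")
  crisp <- if (inherits(lumping, "macrostate_model")) lumping$crisp_map else as.integer(lumping)
  Tm <- model$transition_matrix
  start <- which.max(model$stationary)
  means <- r2s <- numeric(0)
  fallback <- logical(0)
  n_events <- 0L
  fits <- list()
  for (r in seq_len(n_replicas)) {
    chain <- sample_discrete_chain(Tm, n_steps = steps_per_replica,
                                   seed = derive_seed(seed, r), start_state = start)
    macro <- crisp[chain]
    fps <- collect_first_passages(macro, source, target, tau = model$lag_time,
                                  replica_id = r)
    if (length(fps$times) == 0L) {
      warning(sprintf("replica %d has no passage events; dropped", r))
      next
    }
    n_events <- n_events + length(fps$times)
    fit <- tryCatch(fit_fpt_poisson(fps, ...), error = function(e) NULL)
    if (is.null(fit)) {
      means <- c(means, mean(fps$times))
      r2s <- c(r2s, NA_real_)
      fallback <- c(fallback, TRUE)
      fits[[length(fits) + 1L]] <- list(replica = r, fallback = TRUE,
                                        mean = mean(fps$times))
    } else {
      means <- c(means, fit$mean)
      r2s <- c(r2s, fit$r2)
      fallback <- c(fallback, FALSE)
      fits[[length(fits) + 1L]] <- c(list(replica = r, fallback = FALSE),
                                     unclass(fit))
    }
  }
  if (length(means) == 0L) stop("no replica produced any passage events")
  structure(list(
    replica_means = means,
    replica_average = mean(means),
    standard_error = if (length(means) > 1L) stats::sd(means) / sqrt(length(means)) else NA_real_,
    n_events = n_events,
    regression_r2 = mean(r2s, na.rm = TRUE),
    fallback = fallback,
    fits = fits,
    source = source, target = target
  ), class = "mfpt_estimate")
}

#' @export
print.mfpt_estimate <- function(x, ...) {
  cat(sprintf("mfpt_estimate: %s -> %s = %.5g +/- %.3g (%d replicas, %d events)\n",
              paste(x$source, collapse = ","), paste(x$target, collapse = ","),
              x$replica_average, x$standard_error, length(x$replica_means),
              x$n_events))
  invisible(x)
}

#' Upper bound on a macrostate MFPT from untruncated microstate MFPTs
#'
#' Solves the untruncated per-microstate MFPTs to the target macrostate's
#' members and returns their stationary-weighted average over the source
#' macrostate's members (weights renormalized within the source). When
#' macrostate-level markovianity fails, slow microstate transitions dominate
#' this estimate, which therefore bounds the macrostate MFPT from above; for
#' a perfectly lumpable chain it agrees with the macrostate-level linear
#' solve, and for singleton macrostates the two are identical.
#'
#' @inheritParams mfpt_mc
#' @return Upper-bound MFPT in `lag_time` units.
#' @export
mfpt_upper_bound <- function(model, lumping, source, target) {
  crisp <- if (inherits(lumping, "macrostate_model")) lumping$crisp_map else as.integer(lumping)
  src_micro <- which(crisp %in% source)
  tgt_micro <- which(crisp %in% target)
  if (length(src_micro) == 0L || length(tgt_micro) == 0L)
    stop("empty source or target macrostate")
  mfpt_solve(model, src_micro, tgt_micro)
}
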