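# Trajectory-mapping (TM) slow-mode analysis: non-overlapping trajectory
# segments are mapped to their time-averaged feature vectors; principal
# components of the segment-mean matrix are the slow-mode loadings, and the
# relaxation of their per-frame projections gives mode timescales. This is
# the standard independent cross-check of an MSM built on a different metric.

#' Trajectory-mapping slow modes
#'
#' Splits each trajectory into non-overlapping segments of `segment_length`
#' frames (partial tails dropped), averages the features within each segment,
#' and takes principal components of the centered segment-mean matrix as the
#' slow-mode loadings. Per-frame projections apply the loadings to the
#' centered frames. Each loading vector is oriented so its largest-magnitude
#' entry is positive.
#'
#' @param features a `feature_series` or a list of them (one per trajectory).
#' @param segment_length segment length in frames (>= 2); default 10% of the
#'   shortest trajectory.
#' @param n_modes number of modes to keep; default all (bounded by
#'   `n_segments - 1`).
#' @return An object of class `tm_result`: list with `segment_length`,
#'   `segment_means`, `loadings` (features x modes, orthonormal),
#'   `mode_variances` (non-increasing), `projections` (list, one
#'   n_frames x n_modes matrix per trajectory), `center`, `frame_interval`.
#' @export
trajectory_map <- function(features, segment_length = NULL, n_modes = NULL) {
  if (inherits(features, "feature_series")) features <- list(features)
  stopifnot(all(vapply(features, inherits, TRUE, "feature_series")))
  n_frames <- vapply(features, function(f) nrow(f$values), 0L)
  if (is.null(segment_length)) segment_length <- max(2L, floor(min(n_frames) / 10))
  segment_length <- as.integer(segment_length)
  if (segment_length < 2L) stop("segment_length must be >= 2 frames")
  seg_means <- list()
  for (f in features) {
    ns <- nrow(f$values) %/% segment_length
    if (ns < 1L) stop("a trajectory yields no full segment at this segment length")
    grp <- rep(seq_len(ns), each = segment_length)
    seg_means[[length(seg_means) + 1L]] <-
      rowsum(f$values[seq_len(ns * segment_length), , drop = FALSE], grp) / segment_length
  }
  M <- do.call(rbind, seg_means)
  if (nrow(M) < 2L)
    stop("need at least 2 segments in total; shorten segment_length or add trajectories")
  max_modes <- min(nrow(M) - 1L, ncol(M))
  if (is.null(n_modes)) n_modes <- max_modes
  if (n_modes > max_modes)
    stop(sprintf("requested %d modes but only %d segments are available",
                 n_modes, nrow(M)))
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  W <- pc$rotation[, seq_len(n_modes), drop = FALSE]
  # deterministic sign: largest-magnitude entry of each loading positive
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  ctr <- pc$center
  projections <- lapply(features, function(f)
    sweep(f$values, 2, ctr) %*% W)
  structure(list(
    segment_length = segment_length,
    segment_means = M,
    loadings = W,
    mode_variances = pc$sdev[seq_len(n_modes)]^2,
    projections = projections,
    center = ctr,
    frame_interval = features[[1]]$frame_interval
  ), class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("tm_result: %d segments of %d frames, %d modes\n",
              nrow(x$segment_means), x$segment_length, ncol(x$loadings)))
  var_frac <- x$mode_variances / sum(x$mode_variances)
  cat(sprintf("  mode variance fractions: %s\n",
              paste(sprintf("%.2f", var_frac), collapse = ", ")))
  invisible(x)
}

#' Relaxation timescale of a slow-mode projection
#'
#' Autocorrelation of the mode projection at lags `1..max_lag`, computed
#' within each trajectory (never across boundaries) about the pooled mean and
#' pooled for the estimate; the discrete relaxation at lag l gives
#' \eqn{\tau(l) = -l\,\Delta t / \ln \rho(l)}. The reported timescale is the
#' value at the largest lag with a positive autocorrelation; a plateau flag
#' records whether the curve has levelled off (last two valid lags within
#' 20%).
#'
#' @param tm a `tm_result`, or a list of numeric projection vectors.
#' @param mode mode index when `tm` is a `tm_result` (default 1, the slowest).
#' @param max_lag largest lag (frames); at least 10x `max_lag` frames must be
#'   available in aggregate.
#' @param frame_interval time per frame (taken from `tm` when available).
#' @return List with `timescale`, `plateau`, and `curve` (data.frame `lag`,
#'   `rho`, `tau`, `flag`).
#' @export
mode_timescale <- function(tm, mode = 1L, max_lag = 50L, frame_interval = NULL) {
  if (inherits(tm, "tm_result")) {
    proj <- lapply(tm$projections, function(p) p[, mode])
    frame_interval <- frame_interval %||% tm$frame_interval
  } else {
    proj <- if (is.list(tm)) tm else list(tm)
    frame_interval <- frame_interval %||% 1
  }
  n_tot <- sum(lengths(proj))
  if (n_tot < 10L * max_lag)
    stop("need at least 10 * max_lag frames in aggregate")
  mu <- mean(unlist(proj))
  v0 <- sum(vapply(proj, function(p) sum((p - mu)^2), 0))
  if (v0 == 0) stop("projection has zero variance; no timescale is defined")
  lags <- seq_len(max_lag)
  rho <- vapply(lags, function(l) {
    num <- sum(vapply(proj, function(p) {
      n <- length(p)
      if (n <= l) return(0)
      sum((p[1:(n - l)] - mu) * (p[(l + 1):n] - mu))
    }, 0))
    num / v0
  }, 0)
  tau <- rep(NA_real_, max_lag)
  flag <- ifelse(rho <= 0, "nonpositive", "ok")
  ok <- rho > 0 & rho < 1
  tau[ok] <- -lags[ok] * frame_interval / log(rho[ok])
  valid <- which(ok)
  timescale <- if (length(valid)) tau[max(valid)] else NA_real_
  plateau <- FALSE
  if (length(valid) >= 2L) {
    t2 <- tau[utils::tail(valid, 2)]
    plateau <- abs(diff(t2)) / mean(t2) < 0.2
  }
  list(timescale = timescale, plateau = plateau,
       curve = data.frame(lag = lags, rho = rho, tau = tau, flag = flag))
}
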