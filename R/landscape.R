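# Population-density (-ln P) profiles and maps along reaction coordinates,
# with time-block convergence checks. -ln P is computed on raw per-bin
# probability (no kT scaling); empty bins are masked, not given fake values.

#' One-dimensional population-density profile
#'
#' Histograms the samples and returns \eqn{-\ln(\mathrm{count}/n)} per bin,
#' shifted so the lowest occupied bin sits at 0 (a "potential-like" surface).
#' Empty bins are masked.
#'
#' @param values numeric samples of the coordinate.
#' @param bins number of bins, or an explicit vector of break points.
#' @param range bin range when `bins` is a count; default the data range.
#' @return An object of class `density_profile`: list with `edges`,
#'   `centers`, `counts`, `neg_log_p`, `mask` (TRUE where the bin is empty),
#'   `n_samples`.
#' @export
density_1d <- function(values, bins = 50L, range = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("no samples")
  if (length(bins) == 1L) {
    if (bins < 2L) stop("at least 2 bins are required")
    rg <- range %||% base::range(values)
    if (diff(rg) == 0) rg <- rg + c(-0.5, 0.5)  # all values identical
    edges <- seq(rg[1], rg[2], length.out = bins + 1L)
  } else {
    edges <- sort(bins)
  }
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  counts <- tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
  profile_from_counts(list(edges), counts, length(values))
}

profile_from_counts <- function(edges_list, counts, n_samples) {
  mask <- counts == 0
  nlp <- rep(NA_real_, length(counts))
  nlp[!mask] <- -log(counts[!mask] / n_samples)
  nlp <- nlp - min(nlp, na.rm = TRUE)
  centers_list <- lapply(edges_list, function(e) (e[-1] + e[-length(e)]) / 2)
  structure(list(
    edges = if (length(edges_list) == 1L) edges_list[[1]] else edges_list,
    centers = if (length(centers_list) == 1L) centers_list[[1]] else centers_list,
    counts = counts, neg_log_p = nlp, mask = mask, n_samples = n_samples,
    ndim = length(edges_list)
  ), class = "density_profile")
}

#' Two-dimensional population-density map
#'
#' @param x,y numeric samples of the two coordinates.
#' @param bins bin count per axis (scalar or length 2), or a list of two
#'   break vectors.
#' @param range optional list of two axis ranges.
#' @return A `density_profile` whose `counts`/`neg_log_p`/`mask` are
#'   `nx x ny` matrices and whose `edges`/`centers` are lists per axis.
#' @export
density_2d <- function(x, y, bins = 50L, range = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (is.list(bins)) {
    ex <- sort(bins[[1]]); ey <- sort(bins[[2]])
  } else {
    if (length(bins) == 1L) bins <- c(bins, bins)
    rx <- (range[[1]] %||% base::range(x)); ry <- (range[[2]] %||% base::range(y))
    if (diff(rx) == 0) rx <- rx + c(-0.5, 0.5)
    if (diff(ry) == 0) ry <- ry + c(-0.5, 0.5)
    ex <- seq(rx[1], rx[2], length.out = bins[1] + 1L)
    ey <- seq(ry[1], ry[2], length.out = bins[2] + 1L)
  }
  ix <- findInterval(x, ex, rightmost.closed = TRUE)
  iy <- findInterval(y, ey, rightmost.closed = TRUE)
  nx <- length(ex) - 1L; ny <- length(ey) - 1L
  ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  counts <- matrix(tabulate((iy[ok] - 1L) * nx + ix[ok], nbins = nx * ny), nx, ny)
  prof <- profile_from_counts(list(ex, ey), as.numeric(counts), length(x))
  prof$counts <- counts
  prof$neg_log_p <- matrix(prof$neg_log_p, nx, ny)
  prof$mask <- matrix(prof$mask, nx, ny)
  prof
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile (%d-D): %d samples, %d occupied / %d bins\n",
              x$ndim, x$n_samples, sum(!x$mask), length(x$counts)))
  invisible(x)
}

# Jensen-Shannon divergence between two count vectors (natural log).
# Zeros are tolerated: 0 log 0 = 0.
js_divergence <- function(c1, c2) {
  p <- c1 / sum(c1); q <- c2 / sum(c2)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Time-block convergence test of a sampled density
#'
#' Builds the density profile of a coordinate over several time windows of
#' the ensemble (identical bins across windows) and scores their mutual
#' Jensen-Shannon divergence. When sampling has converged, profiles from
#' late windows agree and the divergence approaches the resampling noise
#' floor; dropping early (burn-in) data should lower it.
#'
#' @param ensemble list of [trajectory()] objects.
#' @param coordinate column index into the frames, or a function mapping a
#'   frame matrix to a numeric vector.
#' @param windows list of `c(t_start, t_end)` time ranges (same units as the
#'   trajectories' `frame_interval`).
#' @param bins number of bins (shared across windows).
#' @return List with `profiles` (one `density_profile` per window),
#'   `divergence` (mean pairwise JS divergence), and `pairwise` (matrix).
#' @export
convergence_blocks <- function(ensemble, coordinate, windows, bins = 50L) {
  if (inherits(ensemble, "trajectory")) ensemble <- list(ensemble)
  getval <- if (is.function(coordinate)) coordinate
            else function(fr) fr[, coordinate]
  vals <- lapply(ensemble, function(tr) getval(tr$frames))
  times <- lapply(ensemble, function(tr)
    (seq_len(nrow(tr$frames)) - 1L) * tr$frame_interval)
  window_values <- lapply(seq_along(windows), function(wi) {
    w <- windows[[wi]]
    v <- unlist(lapply(seq_along(vals), function(i) {
      vals[[i]][times[[i]] >= w[1] & times[[i]] <= w[2]]
    }))
    if (length(v) == 0L)
      stop(sprintf("window %d [%g, %g] contains no frames", wi, w[1], w[2]))
    v
  })
  rg <- base::range(unlist(window_values))
  profiles <- lapply(window_values, density_1d, bins = bins, range = rg)
  nw <- length(profiles)
  pw <- matrix(0, nw, nw)
  for (i in seq_len(nw)) for (j in seq_len(nw)) if (i < j)
    pw[i, j] <- pw[j, i] <- js_divergence(profiles[[i]]$counts,
                                          profiles[[j]]$counts)
  list(profiles = profiles,
       divergence = if (nw > 1L) mean(pw[upper.tri(pw)]) else 0,
       pairwise = pw)
}
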