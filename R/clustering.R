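# Greedy K-center clustering of trajectory frames under a pluggable metric.
# Distances are computed one center at a time against all frames (streaming);
# no all-pairs matrix is ever materialized, so 1e6-frame ensembles stay
# memory-safe.

resolve_metric_coords <- function(frames, metric) {
  if (is.null(metric)) {
    frames <- as.matrix(frames)
    list(coords = frames, scale = 1)
  } else {
    stopifnot(inherits(metric, "metric_spec"))
    prepare_metric_coords(frames, metric)
  }
}

dist_to_point <- function(coords, center_row, scale) {
  d <- sqrt(rowSums(sweep(coords, 2, center_row)^2)) / scale
  if (!all(is.finite(d)))
    stop("non-finite distance for frame(s) ",
         paste(utils::head(which(!is.finite(d)), 5), collapse = ", "))
  d
}

#' Greedy K-center clustering
#'
#' Covers the frame set with `k` centers by the classical greedy scheme:
#' start from a deterministic initial center, then repeatedly promote the
#' frame farthest from its nearest existing center. The maximum cluster
#' radius is guaranteed to be at most twice the optimal k-center radius.
#' Ties in the farthest-point choice break to the lowest frame index.
#'
#' @param frames frame matrix (n_frames x n_features) or coordinate array
#'   (n_frames x n_points x 3) when `metric` aligns frames.
#' @param k number of clusters, `1 <= k <= n_frames`.
#' @param metric optional [metric_spec()]; default Euclidean distance on the
#'   rows of `frames`.
#' @param seed optional integer; when given with `init = "random"`, picks the
#'   initial center at random. The default initialization is frame 1.
#' @param init `"first"` (deterministic, default) or `"random"`.
#' @return An object of class `microstate_model` with fields `n_clusters`,
#'   `center_frame_ids`, `assignments`, `radii`, `mean_within_cluster_distance`,
#'   plus the prepared center coordinates used by [assign_frames()].
#' @export
kcenter <- function(frames, k, metric = NULL, seed = NULL,
                    init = c("first", "random")) {
  init <- match.arg(init)
  prep <- resolve_metric_coords(frames, metric)
  X <- prep$coords
  n <- nrow(X)
  if (k < 1L || k > n) stop("k must be between 1 and the number of frames")
  centers <- integer(k)
  if (init == "random") {
    if (is.null(seed)) stop("random initialization needs a seed")
    set.seed(seed)
    centers[1] <- sample.int(n, 1L)
  } else {
    centers[1] <- 1L
  }
  nearest_d <- dist_to_point(X, X[centers[1], ], prep$scale)
  assignments <- rep(1L, n)
  if (k > 1L) {
    for (c in 2:k) {
      centers[c] <- which.max(nearest_d)  # ties -> lowest index
      d <- dist_to_point(X, X[centers[c], ], prep$scale)
      upd <- d < nearest_d
      nearest_d[upd] <- d[upd]
      assignments[upd] <- c
      assignments[centers[c]] <- c
      nearest_d[centers[c]] <- 0
    }
  }
  radii <- vapply(seq_len(k), function(c) {
    m <- nearest_d[assignments == c]
    if (length(m)) max(m) else 0
  }, 0)
  structure(list(
    n_clusters = k,
    center_frame_ids = centers,
    assignments = assignments,
    radii = radii,
    mean_within_cluster_distance = mean(nearest_d),
    center_coords = X[centers, , drop = FALSE],
    metric_scale = prep$scale
  ), class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("microstate_model: %d clusters over %d frames; mean within-cluster distance %.4g, max radius %.4g\n",
              x$n_clusters, length(x$assignments),
              x$mean_within_cluster_distance, max(x$radii)))
  invisible(x)
}

#' Assign frames to the nearest microstate center
#'
#' Nearest-center labels under the model's metric; idempotent on the frames
#' the model was trained on.
#'
#' @param frames frames as in [kcenter()].
#' @param model a `microstate_model`.
#' @param metric the same [metric_spec()] the model was built with (NULL for
#'   Euclidean).
#' @return Integer cluster labels in `1..n_clusters`.
#' @export
assign_frames <- function(frames, model, metric = NULL) {
  prep <- resolve_metric_coords(frames, metric)
  X <- prep$coords
  if (ncol(X) != ncol(model$center_coords))
    stop("frame dimensionality does not match the model's centers")
  n <- nrow(X)
  best_d <- rep(Inf, n)
  labels <- rep(1L, n)
  for (c in seq_len(model$n_clusters)) {
    d <- dist_to_point(X, model$center_coords[c, ], prep$scale)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    labels[upd] <- c
  }
  labels
}
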