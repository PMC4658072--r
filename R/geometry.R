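# Conformational distance metric: rigid-body superposition on an alignment
# subset (Kabsch, SVD with reflection guard) followed by RMSD over a
# measurement subset, plus inter-point distance features.

#' Define a conformational metric
#'
#' The metric aligns every frame to one fixed reference on an alignment
#' subset of points and measures RMSD over a (possibly different) measurement
#' subset — the standard "align on the scaffold, measure the ligand" scheme.
#' For low-dimensional feature data with no atomic structure, omit
#' `alignment_indices`: the metric then degenerates to plain Euclidean
#' distance over the measurement columns.
#'
#' @param reference_frame reference coordinates: an n_points x 3 matrix for
#'   atomic frames, or ignored (may be NULL) for the feature-space metric.
#' @param alignment_indices indices (1-based) of the points used for rigid
#'   superposition; at least 3 non-collinear points. NULL selects the
#'   feature-space (no alignment) code path.
#' @param measurement_indices indices of the points (or feature columns) the
#'   RMSD/distance is measured over. Defaults to all.
#' @return An object of class `metric_spec`.
#' @export
metric_spec <- function(reference_frame = NULL, alignment_indices = NULL,
                        measurement_indices = NULL) {
  if (!is.null(alignment_indices)) {
    if (is.null(reference_frame)) stop("an alignment metric needs a reference_frame")
    reference_frame <- as.matrix(reference_frame)
    if (ncol(reference_frame) != 3L)
      stop("alignment metrics require 3-D frames (n_points x 3)")
    if (length(alignment_indices) < 3L)
      stop("alignment needs at least 3 points")
    check_not_collinear(reference_frame[alignment_indices, , drop = FALSE],
                        alignment_indices)
    if (is.null(measurement_indices))
      measurement_indices <- seq_len(nrow(reference_frame))
  } else if (is.null(measurement_indices) && !is.null(reference_frame)) {
    measurement_indices <- seq_len(ncol(as.matrix(reference_frame)))
  }
  structure(list(reference_frame = reference_frame,
                 alignment_indices = alignment_indices,
                 measurement_indices = measurement_indices),
            class = "metric_spec")
}

check_not_collinear <- function(pts, indices) {
  centered <- sweep(pts, 2, colMeans(pts))
  s <- svd(centered, nu = 0, nv = 0)$d
  if (s[2] < 1e-10 * max(s[1], 1e-30))
    stop("alignment points are degenerate (collinear or coincident): indices ",
         paste(indices, collapse = ", "))
  invisible(TRUE)
}

# Optimal rotation (Kabsch): returns the 3x3 matrix R minimizing
# |mobile %*% R - ref| over the given rows, with a determinant correction so
# reflections are never returned.
kabsch_rotation <- function(mobile_centered, ref_centered) {
  H <- crossprod(mobile_centered, ref_centered)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}

#' Superpose a frame onto the metric's reference
#'
#' Applies the rotation + translation that minimizes the RMSD over the
#' alignment subset (closed-form least squares via SVD of the covariance,
#' with a reflection guard). The minimum is global over all rigid transforms.
#'
#' @param mobile n_points x 3 coordinate matrix.
#' @param spec a [metric_spec()] with alignment indices.
#' @return The transformed `mobile` frame.
#' @export
superpose <- function(mobile, spec) {
  stopifnot(inherits(spec, "metric_spec"))
  if (is.null(spec$alignment_indices))
    stop("this metric has no alignment subset; superposition is undefined")
  mobile <- as.matrix(mobile)
  ref <- spec$reference_frame
  if (!all(dim(mobile) == dim(ref))) stop("mobile and reference dimensions differ")
  ai <- spec$alignment_indices
  mob_a <- mobile[ai, , drop = FALSE]
  ref_a <- ref[ai, , drop = FALSE]
  check_not_collinear(mob_a, ai)
  mc <- colMeans(mob_a)
  rc <- colMeans(ref_a)
  R <- kabsch_rotation(sweep(mob_a, 2, mc), sweep(ref_a, 2, rc))
  sweep(sweep(mobile, 2, mc) %*% R, 2, rc, `+`)
}

#' Alignment-subset RMSD to the reference
#'
#' Superposes `mobile` on the alignment subset, then returns the RMSD over
#' the measurement subset only. Note the reference is fixed: this quantity is
#' a property of (mobile, reference) and is not symmetric under swapping the
#' roles of the two frames.
#'
#' @inheritParams superpose
#' @return RMSD (length units) over the measurement subset.
#' @export
subset_rmsd <- function(mobile, spec) {
  if (is.null(spec$alignment_indices)) {
    # feature-space degenerate path: Euclidean distance over measurement cols
    mi <- spec$measurement_indices %||% seq_along(mobile)
    d <- as.numeric(mobile)[mi] - as.numeric(spec$reference_frame)[mi]
    return(sqrt(mean(d^2)))
  }
  aligned <- superpose(mobile, spec)
  mi <- spec$measurement_indices
  d <- aligned[mi, , drop = FALSE] - spec$reference_frame[mi, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Prepare frames for metric distance computations
#'
#' For an alignment metric, superposes every frame onto the reference and
#' flattens the measurement subset into a feature row, so that the clustering
#' distance between two prepared rows is `|a - b| / sqrt(n_points)` — the
#' measurement-subset RMSD between independently reference-aligned frames.
#' For the feature-space metric, selects the measurement columns unchanged.
#'
#' @param frames either a matrix (n_frames x n_features) for feature data, or
#'   a 3-D array (n_frames x n_points x 3) of coordinates.
#' @param spec a [metric_spec()].
#' @return List with `coords` (n_frames x m matrix) and `scale` such that
#'   metric distance = Euclidean distance on `coords` divided by `scale`.
#' @keywords internal
#' @export
prepare_metric_coords <- function(frames, spec) {
  if (is.null(spec$alignment_indices)) {
    frames <- as.matrix(frames)
    mi <- spec$measurement_indices %||% seq_len(ncol(frames))
    return(list(coords = frames[, mi, drop = FALSE], scale = sqrt(length(mi))))
  }
  if (length(dim(frames)) != 3L)
    stop("alignment metrics require coordinate frames (n_frames x n_points x 3)")
  n <- dim(frames)[1]
  mi <- spec$measurement_indices
  out <- matrix(NA_real_, n, length(mi) * 3L)
  for (i in seq_len(n)) {
    aligned <- superpose(frames[i, , ], spec)
    out[i, ] <- as.numeric(t(aligned[mi, , drop = FALSE]))
  }
  list(coords = out, scale = sqrt(length(mi)))
}

#' Inter-point distance features along a trajectory
#'
#' Euclidean distance between each listed pair of points, per frame.
#'
#' @param traj a [trajectory()] whose frames are a 3-D coordinate array
#'   (n_frames x n_points x 3), or a coordinate array itself.
#' @param pairs list of length-2 index vectors, or a 2-column matrix.
#' @param frame_interval time between frames (taken from `traj` when it is a
#'   trajectory).
#' @return A `feature_series`: list with `values` (n_frames x n_pairs),
#'   `feature_names` ("d_i_j"), and `frame_interval`.
#' @export
distance_features <- function(traj, pairs, frame_interval = NULL) {
  if (inherits(traj, "trajectory")) {
    frame_interval <- traj$frame_interval
    coords <- traj$frames
  } else {
    coords <- traj
  }
  if (length(dim(coords)) != 3L)
    stop("distance features require coordinate frames (n_frames x n_points x 3)")
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  n_points <- dim(coords)[2]
  vals <- sapply(pairs, function(p) {
    if (any(p < 1L) || any(p > n_points))
      stop(sprintf("distance pair (%d, %d) out of range [1, %d]",
                   p[1], p[2], n_points))
    sqrt(rowSums((coords[, p[1], , drop = FALSE] -
                  coords[, p[2], , drop = FALSE])^2, dims = 1))
  })
  vals <- matrix(vals, nrow = dim(coords)[1])
  nm <- vapply(pairs, function(p) sprintf("d_%d_%d", p[1], p[2]), "")
  feature_series(vals, nm, frame_interval %||% 1)
}

#' Construct a feature series
#'
#' @param values n_frames x n_features numeric matrix.
#' @param feature_names unique names, one per feature column.
#' @param frame_interval time between frames.
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(values, feature_names = NULL, frame_interval = 1) {
  values <- as.matrix(values)
  if (ncol(values) < 1L) stop("a feature series needs at least one feature")
  if (!all(is.finite(values))) stop("feature values contain non-finite entries")
  feature_names <- feature_names %||% paste0("f", seq_len(ncol(values)))
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 frame_interval = frame_interval),
            class = "feature_series")
}
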