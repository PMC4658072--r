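# Plain-text serialization: trajectories as CSV + JSON sidecar, ensembles as
# a directory with a manifest, and CSV/JSON exporters for models and results.

#' Write / read a trajectory as CSV with a JSON sidecar
#'
#' Frames go to `<path>` (one row per frame, columns = coordinates); the
#' frame interval, seed, and divergence flag go to `<path>.json`.
#'
#' @param traj a [trajectory()].
#' @param path CSV file path.
#' @return `path`, invisibly (writer); a [trajectory()] (reader).
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- as.data.frame(traj$frames)
  names(df) <- paste0("x", seq_len(ncol(df)))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(frame_interval = traj$frame_interval, seed = traj$seed,
               diverged = traj$diverged, n_frames = nrow(traj$frames),
               biased = !is.null(traj$bias_record))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  frames <- as.matrix(utils::read.csv(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  trajectory(frames, meta$frame_interval,
             seed = meta$seed %||% NA_integer_,
             diverged = isTRUE(meta$diverged))
}

#' Write / read a trajectory ensemble directory
#'
#' Each trajectory becomes `traj_NNN.csv` (+ sidecar); `manifest.json` lists
#' the files and shared metadata.
#'
#' @param ensemble list of [trajectory()] objects.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly (writer); a list of trajectories (reader).
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("traj_%03d.csv", seq_along(ensemble))
  for (i in seq_along(ensemble))
    write_trajectory_csv(ensemble[[i]], file.path(dir, files[i]))
  jsonlite::write_json(list(files = files, n = length(ensemble)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  lapply(man$files, function(f) read_trajectory_csv(file.path(dir, f)))
}

#' Export a microstate model (JSON metadata + CSV assignments)
#' @param model a `microstate_model`.
#' @param prefix path prefix; writes `<prefix>.json` and
#'   `<prefix>_assignments.csv`.
#' @export
write_microstate_model <- function(model, prefix) {
  jsonlite::write_json(list(n_clusters = model$n_clusters,
                            center_frame_ids = model$center_frame_ids,
                            radii = model$radii,
                            mean_within_cluster_distance = model$mean_within_cluster_distance),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(frame = seq_along(model$assignments),
                              cluster = model$assignments),
                   paste0(prefix, "_assignments.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Export a Markov model (CSV matrices + JSON metadata)
#' @param model a `markov_model`.
#' @param prefix path prefix.
#' @export
write_markov_model <- function(model, prefix) {
  utils::write.csv(model$transition_matrix, paste0(prefix, "_T.csv"),
                   row.names = FALSE)
  utils::write.csv(model$count_matrix, paste0(prefix, "_counts.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(lag = model$lag, lag_time = model$lag_time,
                            active_set = model$active_set,
                            stationary = model$stationary,
                            eigenvalues_mod = Mod(model$eigenvalues),
                            reversible = model$reversible,
                            n_discarded_counts = model$n_discarded_counts),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Export a density profile as tidy CSV
#' @param prof a `density_profile`.
#' @param path CSV path.
#' @export
write_density_profile <- function(prof, path) {
  if (prof$ndim == 1L) {
    df <- data.frame(center = prof$centers, count = prof$counts,
                     neg_log_p = prof$neg_log_p, empty = prof$mask)
  } else {
    g <- expand.grid(center_x = prof$centers[[1]], center_y = prof$centers[[2]])
    df <- data.frame(g, count = as.numeric(prof$counts),
                     neg_log_p = as.numeric(prof$neg_log_p),
                     empty = as.logical(prof$mask))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a macrostate model (CSV memberships + JSON summary)
#' @param model a `macrostate_model`.
#' @param prefix path prefix.
#' @export
write_macrostate_model <- function(model, prefix) {
  chi <- as.data.frame(model$membership)
  names(chi) <- model$state_names
  chi$crisp <- model$crisp_map
  utils::write.csv(chi, paste0(prefix, "_membership.csv"), row.names = FALSE)
  jsonlite::write_json(list(n_macro = model$n_macro,
                            state_names = model$state_names,
                            populations = model$macro_populations),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
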