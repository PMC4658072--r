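# Pipeline orchestration: one configuration, one master seed, stages in
# declared order (synthesize/ingest -> cluster -> MSM validation -> lump ->
# kinetics -> landscapes -> slow modes), with a machine-readable run report.

pipeline_defaults <- function() {
  list(
    preset = NULL,            # "benchmark" or NULL when input_dir is given
    input_dir = NULL,
    seed = 1L,
    out_dir = NULL,
    metric = list(
      # feature columns the clustering metric measures over (0-based in
      # serialized configs is NOT used here: indices are 1-based, as in R);
      # NULL means all columns
      measurement_indices = NULL
    ),
    benchmark = list(
      populations = c(0.53, 0.39, 0.08),
      mfpt_ratio = 5,
      oracle_steps = 5e7,
      oracle_dt = 0.002   # same step as the sampled ensemble, so the oracle
                          # measures the same discretized dynamics
    ),
    synth = list(
      n_pull = 15L,             # biased pull trajectories
      pull_spring = 10,         # restraint stiffness (energy/length^2)
      pull_rate = 0.01,         # restraint speed (length/time)
      pull_save_every = 250L,
      n_seed_clusters = 20L,    # K-center clusters over pooled pull frames
      picks_per_cluster = 5L,   # starts per cluster (20 x 5 = 100 seeds)
      n_steps = 100000L,        # steps per short unbiased trajectory
      dt = 0.002,
      save_every = 50L
    ),
    msm = list(
      microstate_counts = c(50L, 100L, 150L),
      chosen_k = 100L,
      lag_scan = c(1L, 2L, 5L, 10L, 20L),
      lag = 10L,
      k_modes = 3L,
      reversible = FALSE,
      ck_multiples = 1:5,
      ck_states = 6L
    ),
    n_macro = 3L,
    kinetics = list(
      n_replicas = 10L,
      steps_per_replica = 5e5,
      min_events = 50L
    ),
    landscape = list(bins = 60L),
    tm = list(segment_length = NULL, max_lag = 400L)
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ",
         paste(paste(c(path, ""), collapse = "$"), unknown, sep = "", collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]), c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, checks every key against the
#' schema (unknown keys are an error, never silently ignored), fills in
#' defaults, and runs basic consistency checks.
#'
#' @param raw path to a YAML config, or a named list.
#' @return A fully resolved config list of class `pipeline_config`.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw)) {
    if (!file.exists(raw)) stop("config file not found: ", raw)
    raw <- yaml::read_yaml(raw)
  }
  cfg <- merge_config(pipeline_defaults(), as.list(raw))
  if (is.null(cfg$preset) && is.null(cfg$input_dir))
    stop("config must name either a preset or an input_dir")
  if (!is.null(cfg$preset) && !cfg$preset %in% c("benchmark"))
    stop("unknown preset: ", cfg$preset)
  if (!is.null(cfg$input_dir) && !dir.exists(cfg$input_dir))
    stop("input_dir does not exist: ", cfg$input_dir)
  if (length(cfg$msm$lag_scan) == 0L || length(cfg$msm$microstate_counts) == 0L)
    stop("msm$lag_scan and msm$microstate_counts must be non-empty")
  if (is.unsorted(cfg$msm$lag_scan, strictly = TRUE))
    stop("msm$lag_scan must be strictly increasing")
  n_frames <- cfg$synth$n_steps %/% cfg$synth$save_every + 1L
  if (!is.null(cfg$preset) && max(cfg$msm$lag_scan) >= n_frames)
    stop("largest lag in msm$lag_scan is not smaller than the trajectory length")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", class(cfg))
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, under one master seed: trajectory synthesis (or ingestion),
#' K-center clustering with a microstate-count scan, implied-timescale and
#' Chapman-Kolmogorov validation, PCCA+ lumping, macrostate kinetics (linear
#' solve, Monte-Carlo regression with replica errors, upper bound),
#' population-density landscapes with a block convergence test, and
#' trajectory-mapping slow modes. Results are returned in a run report and,
#' when `out_dir` is configured, written as CSV/JSON artifacts.
#'
#' Stage RNG streams are derived from the master seed by a fixed counter
#' scheme, so e.g. changing the kinetics replica count does not perturb the
#' synthesis stage.
#'
#' @param config a `pipeline_config` from [validate_config()], or anything
#'   [validate_config()] accepts.
#' @return A `run_report`: list with `config`, `stages` (per-stage status,
#'   parameters, warnings), `results`, and `status` (0 on success).
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  report <- list(config = config, stages = list(), results = list(), status = 0L)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed) {
      report$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    warnings <- character(0)
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) e),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "error",
                                     message = conditionMessage(res),
                                     warnings = warnings, elapsed = elapsed)
      failed <<- TRUE
      report$status <<- 1L
      return(NULL)
    }
    report$stages[[name]] <<- list(status = "ok", warnings = warnings,
                                   elapsed = elapsed)
    res
  }

  seed <- config$seed
  sy <- config$synth
  bench <- NULL
  ensemble <- NULL

  if (!is.null(config$preset) && config$preset == "benchmark") {
    bench <- run_stage("system", function() {
      make_benchmark_system(populations = config$benchmark$populations,
                            mfpt_ratio = config$benchmark$mfpt_ratio,
                            seed = derive_seed(seed, 100L),
                            dt = config$benchmark$oracle_dt,
                            oracle_steps = config$benchmark$oracle_steps)
    })
    pulls <- run_stage("pull", function() {
      pot <- bench$potential
      span <- diff(range(pot$centers[, 1])) + 0.5
      pull <- pull_spec(direction = c(1, 0), spring_constant = sy$pull_spring,
                        pull_rate = sy$pull_rate, duration = span / sy$pull_rate)
      lapply(seq_len(sy$n_pull), function(i)
        simulate_steered_pull(pot, pull, dt = sy$dt,
                              seed = derive_seed(seed, 110L + i),
                              start = c(pot$centers[1, 1], 0),
                              save_every = sy$pull_save_every))
    })
    starts <- run_stage("seed", function() {
      adaptive_seed(pulls, n_clusters = sy$n_seed_clusters,
                    picks_per_cluster = sy$picks_per_cluster,
                    seed = derive_seed(seed, 130L))
    })
    ensemble <- run_stage("sample", function() {
      lapply(seq_len(nrow(starts)), function(i)
        simulate_langevin(bench$potential, n_steps = sy$n_steps, dt = sy$dt,
                          seed = derive_seed(seed, 200L + i),
                          start = starts[i, ], save_every = sy$save_every))
    })
  } else {
    ensemble <- run_stage("ingest", function() {
      ens <- read_ensemble(config$input_dir)
      if (length(ens) == 0L) stop("input ensemble is empty")
      ens
    })
  }
  if (failed) return(finish_report(report, out_dir))

  frames <- do.call(rbind, lapply(ensemble, function(tr) tr$frames))
  traj_lengths <- vapply(ensemble, function(tr) nrow(tr$frames), 0L)
  frame_interval <- ensemble[[1]]$frame_interval
  mcfg <- config$msm

  cluster_scan <- run_stage("cluster", function() {
    metric <- if (is.null(config$metric$measurement_indices)) NULL
              else metric_spec(reference_frame = frames[1, ],
                               measurement_indices = config$metric$measurement_indices)
    ks <- union(mcfg$microstate_counts, mcfg$chosen_k)
    models <- lapply(ks, function(k)
      kcenter(frames, k = k, metric = metric, seed = derive_seed(seed, 300L)))
    names(models) <- as.character(ks)
    models
  })
  if (failed) return(finish_report(report, out_dir))
  micro <- cluster_scan[[as.character(mcfg$chosen_k)]]
  seqs_of <- function(model)
    split(model$assignments, rep(seq_along(traj_lengths), traj_lengths))
  label_seqs <- seqs_of(micro)

  its_scan <- run_stage("timescales", function() {
    scans <- lapply(names(cluster_scan), function(kname) {
      curve <- implied_timescales(seqs_of(cluster_scan[[kname]]),
                                  lags = mcfg$lag_scan, k_modes = mcfg$k_modes,
                                  frame_interval = frame_interval,
                                  n_states = cluster_scan[[kname]]$n_clusters,
                                  reversible = mcfg$reversible)
      cbind(data.frame(n_microstates = as.integer(kname)), curve)
    })
    do.call(rbind, scans)
  })

  model <- run_stage("msm", function() {
    C <- count_transitions(label_seqs, mcfg$lag, n_states = micro$n_clusters)
    estimate_markov_model(C, lag = mcfg$lag,
                          lag_time = mcfg$lag * frame_interval,
                          reversible = mcfg$reversible)
  })
  if (failed) return(finish_report(report, out_dir))

  ck <- run_stage("ck", function() {
    chapman_kolmogorov(label_seqs, model, multiples = mcfg$ck_multiples,
                       n_states_tested = mcfg$ck_states)
  })

  lump <- run_stage("lump", function() {
    pcca_plus(model, n_macro = config$n_macro)
  })
  if (failed) return(finish_report(report, out_dir))

  # order macrostates along the escape coordinate (first feature column) so
  # macro 1 is the first basin in the release sequence
  macro_order <- run_stage("macro_order", function() {
    centers_x <- micro$center_coords[model$active_set, 1]
    vapply(seq_len(lump$n_macro), function(j) {
      w <- model$stationary[lump$crisp_map == j]
      sum(w * centers_x[lump$crisp_map == j]) / sum(w)
    }, 0)
  })
  ord <- order(macro_order)  # macro labels sorted along the coordinate

  kin <- run_stage("kinetics", function() {
    kcfg <- config$kinetics
    coarse <- coarse_grain(model, lump)
    transitions <- lapply(seq_len(lump$n_macro - 1L), function(i) {
      src <- ord[i]; tgt <- ord[i + 1L]
      mc <- mfpt_mc(model, lump, source = src, target = tgt,
                    n_replicas = kcfg$n_replicas,
                    steps_per_replica = kcfg$steps_per_replica,
                    seed = derive_seed(seed, 400L + i),
                    min_events = kcfg$min_events)
      list(
        from = i, to = i + 1L,
        linear_solve = mfpt_solve(coarse, src, tgt),
        mc_mean = mc$replica_average,
        mc_se = mc$standard_error,
        regression_r2 = mc$regression_r2,
        upper_bound = mfpt_upper_bound(model, lump, src, tgt),
        n_events = mc$n_events)
    })
    transitions
  })

  land <- run_stage("landscape", function() {
    bins <- config$landscape$bins
    x <- frames[, 1]
    total_t <- (max(traj_lengths) - 1) * frame_interval
    out <- list(profile_1d = density_1d(x, bins = bins))
    if (ncol(frames) >= 2L)
      out$map_2d <- density_2d(x, frames[, 2], bins = bins)
    out$convergence <- convergence_blocks(
      ensemble, 1L,
      windows = list(c(0, total_t), c(0.25 * total_t, total_t),
                     c(0.5 * total_t, total_t)),
      bins = bins)
    out
  })

  tm_res <- run_stage("tm", function() {
    anchors <- tm_anchor_points(frames)
    feats <- lapply(ensemble, function(tr) {
      vals <- sapply(seq_len(nrow(anchors)), function(a)
        sqrt(rowSums(sweep(tr$frames, 2, anchors[a, ])^2)))
      feature_series(vals, paste0("d_anchor", seq_len(nrow(anchors))),
                     frame_interval = tr$frame_interval)
    })
    tmap <- trajectory_map(feats, segment_length = config$tm$segment_length)
    ts <- mode_timescale(tmap, mode = 1L, max_lag = config$tm$max_lag)
    list(tm = tmap, timescale = ts)
  })

  report$results <- list(
    benchmark = bench,
    n_trajectories = length(ensemble),
    n_frames = nrow(frames),
    microstates = micro,
    timescale_scan = its_scan,
    model = model,
    ck = ck,
    lumping = lump,
    macro_populations_ordered =
      if (!is.null(lump)) lump$macro_populations[ord] else NULL,
    macro_order = ord,
    kinetics = kin,
    landscape = land,
    slow_modes = tm_res
  )
  finish_report(report, out_dir)
}

# Anchor battery for the synthetic TM feature set: distances to fixed points
# spread over the sampled range of the first two coordinates.
tm_anchor_points <- function(frames) {
  r1 <- range(frames[, 1])
  if (ncol(frames) >= 2L) {
    r2 <- range(frames[, 2])
    as.matrix(expand.grid(seq(r1[1], r1[2], length.out = 4),
                          seq(r2[1], r2[2], length.out = 2)))
  } else {
    matrix(seq(r1[1], r1[2], length.out = 5), ncol = 1)
  }
}

finish_report <- function(report, out_dir) {
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    res <- report$results
    if (!is.null(res$microstates))
      write_microstate_model(res$microstates, file.path(out_dir, "microstates"))
    if (!is.null(res$model))
      write_markov_model(res$model, file.path(out_dir, "msm"))
    if (!is.null(res$timescale_scan))
      utils::write.csv(res$timescale_scan,
                       file.path(out_dir, "implied_timescales.csv"),
                       row.names = FALSE)
    if (!is.null(res$ck))
      utils::write.csv(res$ck, file.path(out_dir, "ck_report.csv"),
                       row.names = FALSE)
    if (!is.null(res$lumping))
      write_macrostate_model(res$lumping, file.path(out_dir, "macrostates"))
    if (!is.null(res$kinetics))
      jsonlite::write_json(res$kinetics, file.path(out_dir, "mfpt.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(res$landscape)) {
      write_density_profile(res$landscape$profile_1d,
                            file.path(out_dir, "density_1d.csv"))
      if (!is.null(res$landscape$map_2d))
        write_density_profile(res$landscape$map_2d,
                              file.path(out_dir, "density_2d.csv"))
    }
    stage_summary <- lapply(report$stages, function(s)
      s[setdiff(names(s), "result")])
    jsonlite::write_json(list(seed = report$config$seed,
                              status = report$status,
                              stages = stage_summary),
                         file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (status", x$status, ")\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-12s %s%s\n", nm, s$status,
                if (!is.null(s$message)) paste0(": ", s$message) else ""))
  }
  if (!is.null(x$results$macro_populations_ordered)) {
    cat("  macrostate populations (escape-ordered): ",
        paste(sprintf("%.3f", x$results$macro_populations_ordered),
              collapse = " / "), "\n")
    for (tr in x$results$kinetics)
      cat(sprintf("  MFPT %d->%d: solve %.4g, MC %.4g +/- %.3g, upper bound %.4g\n",
                  tr$from, tr$to, tr$linear_solve, tr$mc_mean, tr$mc_se,
                  tr$upper_bound))
  }
  invisible(x)
}
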