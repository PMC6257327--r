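# Orchestration: the whole analysis from one configuration, writing every
# artifact (energy matrix, hydrogen-bond matrices, RMSD dissimilarity,
# summary, entropy, stages, contact map, per-frame classification and a
# run manifest) into an output directory.

#' Analysis configuration for [run_pipeline()]
#'
#' @param topology path to the topology PDB.
#' @param trajectory path to the multi-model PDB trajectory.
#' @param parameters path to the force-field parameter file (JSON/YAML).
#' @param out output directory (created if absent).
#' @param temperature analysis temperature, K.
#' @param dt spacing of the stored trajectory frames, ps.
#' @param interval_ps sampling interval, ps (`NULL`: keep all frames).
#' @param window_ns sampling window, ns (`NULL`: keep all frames).
#' @param solvation a [solvation_config()].
#' @param hbond_dist,hbond_angle hydrogen-bond criteria (A, degrees).
#' @param contact_cutoff side-chain contact cutoff, A.
#' @param smoothing_window odd moving-average window, frames.
#' @param rmsd logical: compute the per-monomer RMSD dissimilarity
#'   matrices (quadratic in frames; disable for very long runs).
#' @param classifier a [classifier_control()].
#' @param seed integer seed echoed into the manifest (the analysis itself
#'   is deterministic).
#' @return List of class `"analysis_config"`.
#' @export
analysis_config <- function(topology, trajectory, parameters, out,
                            temperature = 305, dt = 4, interval_ps = NULL,
                            window_ns = NULL, solvation = solvation_config(),
                            hbond_dist = 3.5, hbond_angle = 120,
                            contact_cutoff = 6.5, smoothing_window = 101,
                            rmsd = TRUE, classifier = classifier_control(),
                            seed = 1) {
  structure(list(topology = topology, trajectory = trajectory,
                 parameters = parameters, out = out,
                 temperature = temperature, dt = dt,
                 interval_ps = interval_ps, window_ns = window_ns,
                 solvation = solvation, hbond_dist = hbond_dist,
                 hbond_angle = hbond_angle, contact_cutoff = contact_cutoff,
                 smoothing_window = smoothing_window, rmsd = rmsd,
                 classifier = classifier, seed = seed),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Top-level keys mirror the [analysis_config()] arguments; `solvation`
#' and `classifier` are nested maps passed to [solvation_config()] and
#' [classifier_control()].
#'
#' @param file YAML path.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(file) {
  y <- yaml::read_yaml(file)
  y$solvation <- do.call(solvation_config, y$solvation %||% list())
  y$classifier <- do.call(classifier_control, y$classifier %||% list())
  do.call(analysis_config, y)
}

.stage_log <- function(quiet, ...) if (!quiet) message(...)

#' Run the full dimer analysis pipeline
#'
#' Reads topology/trajectory/parameters, optionally resamples the
#' trajectory, and writes: the n x 18 energy matrix, the Table-1-style
#' summary, the entropy report, the stage report, the hydrogen-bond
#' presence matrix / density series / occupancy table, the per-monomer
#' RMSD dissimilarity matrices, the side-chain contact map, the per-frame
#' conformation classification and a JSON run manifest.  Any stage
#' failure aborts with the stage name.
#'
#' @param config an [analysis_config()] or the path to its YAML form.
#' @param quiet suppress progress messages.
#' @return Invisibly, a named list of the written file paths plus the
#'   in-memory [mmpbsa()] result.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_analysis_config(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  step <- function(name, expr) {
    .stage_log(quiet, "[dimerbind] ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  top <- step("read topology", read_topology(config$topology))
  traj <- step("read trajectory",
               read_trajectory(config$trajectory, top, dt = config$dt))
  ff <- step("read force field", read_forcefield(config$parameters, top))
  if (!is.null(config$interval_ps) && !is.null(config$window_ns))
    traj <- step("sample frames",
                 sample_frames(traj, config$interval_ps, config$window_ns))
  fit <- step("energy decomposition",
              mmpbsa(traj, ff, config$solvation, config$temperature,
                     smoothing_window = config$smoothing_window))
  out <- function(f) file.path(config$out, f)
  step("write energy matrix", {
    write_energy_matrix(fit$energy, out("energy_matrix.csv"))
    paths$energy_matrix <- out("energy_matrix.csv")
  })
  step("write summary", {
    write.csv(as.data.frame(fit$summary), out("summary.csv"), row.names = FALSE)
    paths$summary <- out("summary.csv")
  })
  step("write entropy report", {
    ent <- fit$entropy
    df <- data.frame(species = c("complex", "A", "B", "correction"),
                     minus_t_s = c(ent$complex$minus_t_s, ent$A$minus_t_s,
                                   ent$B$minus_t_s, ent$correction))
    write.csv(df, out("entropy.csv"), row.names = FALSE)
    paths$entropy <- out("entropy.csv")
  })
  step("write stage report", {
    st <- if (is.null(fit$stages))
      data.frame(stage = character(0), from = integer(0), to = integer(0),
                 mean_de_mm = numeric(0), mean_de_sol = numeric(0))
    else fit$stages$stages
    st$from_ns <- attr(fit$energy, "time")[st$from] / 1000
    st$to_ns <- attr(fit$energy, "time")[st$to] / 1000
    write.csv(st, out("stages.csv"), row.names = FALSE)
    paths$stages <- out("stages.csv")
  })
  pm <- step("hydrogen bonds", {
    pm <- hbond_presence_matrix(traj, config$hbond_dist, config$hbond_angle)
    df <- data.frame(time_ps = traj$time, unclass(pm)[, , drop = FALSE],
                     check.names = FALSE)
    write.csv(df, out("hbond_presence.csv"), row.names = FALSE)
    paths$hbond_presence <- out("hbond_presence.csv")
    w <- min(config$smoothing_window, n_frames(traj))
    if (w %% 2 == 0) w <- w - 1
    dens <- hbond_density(pm, max(1, w))
    write.csv(data.frame(time_ps = traj$time, dens), out("hbond_density.csv"),
              row.names = FALSE)
    paths$hbond_density <- out("hbond_density.csv")
    occ <- hbond_occupancy(pm, top_n = min(5, ncol(pm)))
    write.csv(occ, out("hbond_occupancy.csv"), row.names = FALSE)
    paths$hbond_occupancy <- out("hbond_occupancy.csv")
    pm
  })
  if (config$rmsd) step("RMSD dissimilarity", {
    for (mono in c("A", "B")) {
      m <- rmsd_dissimilarity_matrix(traj, select_chain(top, mono))
      fn <- out(paste0("rmsd_", mono, ".csv"))
      write.csv(m, fn, row.names = FALSE)
      paths[[paste0("rmsd_", mono)]] <- fn
    }
  })
  step("contact map", {
    cmap <- sidechain_contact_map(traj, cutoff = config$contact_cutoff)
    write.csv(cmap, out("contact_map.csv"))
    paths$contact_map <- out("contact_map.csv")
  })
  step("conformation classification", {
    cls <- vapply(seq_len(n_frames(traj)), function(t)
      classify_dimer_conformation(get_frame(traj, t), top, config$classifier),
      character(1))
    write.csv(data.frame(time_ps = traj$time, class = cls),
              out("classification.csv"), row.names = FALSE)
    paths$classification <- out("classification.csv")
  })
  step("manifest", {
    manifest <- list(package = "dimerbind",
                     version = as.character(packageVersion("dimerbind")),
                     seed = config$seed,
                     n_frames = n_frames(traj),
                     n_hbond_columns = ncol(pm),
                     config = .config_echo(config))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths$manifest <- out("manifest.json")
  })
  invisible(c(paths, list(fit = fit)))
}

.config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$solvation <- unclass(cfg$solvation)
  cfg$classifier <- unclass(cfg$classifier)
  cfg
}
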