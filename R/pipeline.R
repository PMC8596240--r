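#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate/load -> detect -> blank -> PSTH -> response probability
#' -> conduction velocity -> condition comparison, and writes every result
#' table plus a run log. Two runs from the same configuration produce
#' byte-identical outputs.
#'
#' The configuration is a list (or a path to a JSON/YAML file) with:
#' \describe{
#'   \item{seed}{integer; every condition derives its simulation seed from
#'     it.}
#'   \item{conditions}{named list; each entry has either `session_path`
#'     (HDF5 container to load) or `sim` (overrides for [sim_config()])
#'     plus `events` (arguments for [make_stimulus_train()]). `duration_s`
#'     defaults to the end of the stimulus train plus one interval.}
#'   \item{detection}{optional overrides for [detection_config()].}
#'   \item{windows}{optional overrides for [window_config()].}
#'   \item{velocity}{optional list `max_lag_ms`, `min_events`.}
#'   \item{compare}{optional list of two-element vectors of condition names
#'     to compare with [wilcoxon_signed_rank()].}
#'   \item{out_dir}{output directory (may also be given as the `out_dir`
#'     argument).}
#' }
#'
#' Per condition `<name>/` the pipeline writes `spikes.csv`,
#' `probability.csv`, `psth.csv` (long format), `summary.json`,
#' `velocity.csv`, `truth_spikes.csv` and `truth_outcomes.csv` (simulated
#' conditions only); at the top level `stats.json` and `run_log.json`.
#'
#' @param config list or path to a JSON/YAML configuration file.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with per-condition results (`session`, `truth`,
#'   `spikes`, `psth`, `probability`, `velocity`) and `stats`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (key in c("seed", "conditions"))
    if (is.null(config[[key]])) stop("config is missing required key '", key, "'")
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("config is missing required key 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  layout <- stage("layout", default_layout())
  det_cfg <- stage("detection config",
                   do.call(detection_config, config$detection %||% list()))
  win_cfg <- stage("window config",
                   do.call(window_config, config$windows %||% list()))
  vel_cfg <- config$velocity %||% list()

  cond_names <- names(config$conditions)
  if (is.null(cond_names) || any(cond_names == ""))
    stop("config is missing required key 'conditions' names")

  results <- list()
  prob_tables <- list()
  for (i in seq_along(config$conditions)) {
    nm <- cond_names[i]
    cond_spec <- config$conditions[[i]]
    cond_dir <- file.path(out_dir, nm)
    dir.create(cond_dir, recursive = TRUE, showWarnings = FALSE)

    truth <- NULL
    if (!is.null(cond_spec$session_path)) {
      loaded <- stage(paste0("load '", nm, "'"), read_session(cond_spec$session_path))
      session <- loaded$session
      layout_i <- loaded$layout
    } else if (!is.null(cond_spec$sim)) {
      layout_i <- layout
      sim_args <- cond_spec$sim
      ev_args <- cond_spec$events
      if (is.null(ev_args))
        stop("condition '", nm, "': missing key 'events'")
      events <- stage(paste0("events '", nm, "'"),
                      do.call(make_stimulus_train, ev_args))
      if (is.null(sim_args$duration_s))
        sim_args$duration_s <- max(events$ttl_time_s) +
          (ev_args$interval_s %||% 1)
      if (is.null(sim_args$seed))
        sim_args$seed <- sub_seed(config$seed, 100 + i)
      if (is.null(sim_args$label)) sim_args$label <- nm
      sim <- stage(paste0("simulate '", nm, "'"), {
        cfg <- do.call(sim_config, sim_args)
        simulate_session(layout_i, cfg, events)
      })
      session <- sim$session
      truth <- sim$truth
      write_spike_table(truth$spikes[, c("electrode_id", "time_s")],
                        file.path(cond_dir, "truth_spikes.csv"))
      write.csv(truth$spikes, file.path(cond_dir, "truth_spikes_labeled.csv"),
                row.names = FALSE)
      write.csv(truth$outcomes, file.path(cond_dir, "truth_outcomes.csv"),
                row.names = FALSE)
    } else {
      stop("condition '", nm, "': missing key 'sim' or 'session_path'")
    }

    spikes_raw <- stage(paste0("detect '", nm, "'"),
                        detect_session(session, det_cfg))
    spikes <- stage(paste0("blank '", nm, "'"),
                    blank_artifacts(spikes_raw, session$events,
                                    det_cfg$artifact_blank_ms))
    write_spike_table(spikes, file.path(cond_dir, "spikes.csv"))

    psth <- NULL
    prob <- NULL
    if (nrow(session$events)) {
      psth <- stage(paste0("psth '", nm, "'"),
                    compute_psth(spikes, session$events, layout_i, win_cfg))
      starts <- psth$bin_edges_ms[-length(psth$bin_edges_ms)]
      psth_long <- data.frame(
        electrode_id = rep(psth$electrode_ids, times = length(starts)),
        bin_start_ms = rep(starts, each = length(psth$electrode_ids)),
        count = as.vector(psth$counts))
      write.csv(psth_long, file.path(cond_dir, "psth.csv"), row.names = FALSE)

      prob <- stage(paste0("probability '", nm, "'"),
                    response_probability(spikes, session$events, layout_i,
                                         win_cfg))
      write.csv(prob$table, file.path(cond_dir, "probability.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(mean = prob$mean, sd = prob$sd, n_stimuli = prob$n_stimuli,
             responsive_channels = prob$responsive_channels),
        file.path(cond_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
      prob_tables[[nm]] <- prob
    }

    vel <- stage(paste0("velocity '", nm, "'"), tryCatch(
      velocity_from_trains(spikes, layout_i,
                           max_lag_ms = vel_cfg$max_lag_ms %||% 5,
                           min_events = vel_cfg$min_events %||% 3),
      error = function(e) NULL))
    if (!is.null(vel)) {
      vel_tab <- rbind(
        data.frame(channel_index = as.character(vel$per_channel$channel_index),
                   velocity_mm_s = vel$per_channel$velocity_mm_s,
                   n_events = vel$per_channel$n_events),
        data.frame(channel_index = "mean", velocity_mm_s = vel$mean_mm_s,
                   n_events = sum(vel$per_channel$n_events)))
      write.csv(vel_tab, file.path(cond_dir, "velocity.csv"),
                row.names = FALSE)
    }

    results[[nm]] <- list(session = session, truth = truth, spikes = spikes,
                          psth = psth, probability = prob, velocity = vel)
  }

  stats_out <- list()
  for (cmp in config$compare %||% list()) {
    cmp <- unlist(cmp)
    if (length(cmp) != 2 || !all(cmp %in% names(prob_tables)))
      stop("stage 'compare' failed: comparison must name two conditions ",
           "with probability tables")
    res <- stage(paste0("compare ", cmp[1], " vs ", cmp[2]),
                 wilcoxon_signed_rank(prob_tables[[cmp[1]]],
                                      prob_tables[[cmp[2]]]))
    stats_out[[paste(cmp[1], "vs", cmp[2])]] <-
      list(method = res$method, statistic = res$statistic,
           p_value = res$p_value, n_effective = res$n_effective,
           significant = res$significant)
  }
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)

  log <- list(
    package = "axonmea",
    version = as.character(packageVersion("axonmea")),
    r_version = R.version.string,
    seed = config$seed,
    detection = unclass(det_cfg),
    windows = unclass(win_cfg),
    conditions = cond_names
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(c(results, list(stats = stats_out)))
}

# internal: read a JSON or YAML pipeline configuration
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
}
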