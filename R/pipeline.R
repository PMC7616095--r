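pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    task = list(n_trials = 100),
    cohort = list(populations = c("DMS", "DLS", "VLS", "NAcCore"),
                  n_neurons = 8),
    encoding = list(alpha = 0.05),
    clustering = list(k = 4),
    photometry = list(enabled = TRUE),
    td = list(gamma = 0.9, n_states = 5, reward_mean = 5, reward_sd = 5,
              n_neurons = 50, n_training_trials = 10000)
  )
}

#' Validate and default a pipeline configuration
#'
#' Accepts a nested list or a YAML/JSON file path; unknown keys and
#' out-of-range values raise descriptive errors naming the offending path.
#' An empty document yields all defaults.
#'
#' @param raw nested list, YAML/JSON file path, or `NULL` for defaults.
#' @return a validated `run_config` list.
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw) && length(raw) == 1) {
    raw <- if (grepl("\\.json$", raw)) {
      jsonlite::read_json(raw, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(raw)
    }
  }
  raw <- raw %||% list()
  if (!is.list(raw)) stop("config must be a list or a YAML/JSON document")
  defaults <- pipeline_defaults()

  merge_level <- function(def, got, path) {
    unknown <- setdiff(names(got), names(def))
    if (length(unknown)) {
      stop("unknown config key(s): ",
           paste(paste0(path, unknown), collapse = ", "))
    }
    for (nm in names(got)) {
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
        if (!is.list(got[[nm]])) stop("config key ", path, nm, " must be a section")
        def[[nm]] <- merge_level(def[[nm]], got[[nm]], paste0(path, nm, "."))
      } else {
        def[[nm]] <- got[[nm]]
      }
    }
    def
  }
  cfg <- merge_level(defaults, raw, "")

  check_num <- function(x, path, lo = -Inf, hi = Inf, int = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      stop("config key ", path, " must be a number")
    }
    if (x < lo || x > hi) {
      stop("config key ", path, " out of range [", lo, ", ", hi, "]")
    }
    if (int && x != round(x)) stop("config key ", path, " must be an integer")
    x
  }
  check_num(cfg$task$n_trials, "task.n_trials", lo = 1, int = TRUE)
  check_num(cfg$cohort$n_neurons, "cohort.n_neurons", lo = 1, int = TRUE)
  check_num(cfg$encoding$alpha, "encoding.alpha", lo = 0, hi = 1)
  check_num(cfg$clustering$k, "clustering.k", lo = 1, int = TRUE)
  check_num(cfg$td$gamma, "td.gamma", lo = 1e-12, hi = 1)
  check_num(cfg$td$n_states, "td.n_states", lo = 2, int = TRUE)
  check_num(cfg$td$reward_sd, "td.reward_sd", lo = 0)
  check_num(cfg$td$n_neurons, "td.n_neurons", lo = 1, int = TRUE)
  check_num(cfg$td$n_training_trials, "td.n_training_trials", lo = 1, int = TRUE)
  check_num(cfg$seed, "seed", int = TRUE)
  bad_pop <- setdiff(cfg$cohort$populations, c("DMS", "DLS", "VLS", "NAcCore"))
  if (length(bad_pop)) stop("unknown population(s): ", paste(bad_pop, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulate -> encode -> firing statistics -> cluster -> photometry -> TD
#' model, all from one master seed. Stage tables are written as CSV/JSON
#' under `config$out_dir` when set; the returned report summarizes each stage
#' and carries a content hash over all deterministic outputs so identical
#' (config, seed) runs are verifiably identical.
#'
#' @param config a [validate_config()] result (or anything it accepts).
#' @return a `run_report`: per-stage summaries, `provenance` (seed, config,
#'   hash), `timing_s`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  timing <- numeric(0)
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timing[[stage]] <<- t1 - t0
    t0 <<- t1
  }
  task_cfg <- task_config(n_trials = cfg$task$n_trials, seed = cfg$seed)

  # --- simulate ---------------------------------------------------------
  sessions <- list()
  for (i in seq_along(cfg$cohort$populations)) {
    pop <- cfg$cohort$populations[i]
    sessions[[pop]] <- build_population_session(
      pop, cfg$cohort$n_neurons, task_cfg,
      seed = derive_seed(cfg$seed, 1000, i)
    )
  }
  tick("simulate")

  # --- encoding ---------------------------------------------------------
  fits <- list()
  classes <- list()
  for (pop in names(sessions)) {
    ss <- sessions[[pop]]
    for (tr in ss$spike_trains) {
      design <- build_design_matrix(tr, ss$events)
      fit <- fit_poisson_encoding_glm(design)
      fits[[tr$unit_id]] <- fit
      classes[[tr$unit_id]] <- classify_encoding(fit, cfg$encoding$alpha)
    }
  }
  encoding_tab <- write_encoding_csv(fits, classes)
  tick("encode")

  # --- firing statistics ------------------------------------------------
  firing_rows <- list()
  for (pop in names(sessions)) {
    ss <- sessions[[pop]]
    for (tr in ss$spike_trains) {
      fs <- iti_firing_summary(tr, ss$events)
      firing_rows[[tr$unit_id]] <- data.frame(
        unit_id = tr$unit_id, population = pop,
        iti_rate_hz = fs$iti_rate_hz, mean_cv2 = fs$mean_cv2,
        burst_fraction = fs$burst_fraction, n_pauses = fs$n_pauses,
        median_pause_s = fs$median_pause_s)
    }
  }
  firing_tab <- do.call(rbind, firing_rows)
  tick("firing")

  # --- clustering -------------------------------------------------------
  mats <- lapply(names(sessions), function(pop) {
    psth_matrix(sessions[[pop]]$spike_trains, sessions[[pop]]$events)
  })
  big <- do.call(rbind, mats)
  scores <- extract_pcs(big)
  dend <- hcluster_average_euclidean(scores)
  k <- min(cfg$clustering$k, nrow(big))
  assignment <- cut_dendrogram(dend, k)
  labels <- sub("_[0-9]+$", "", rownames(big))
  enrichment <- population_enrichment(assignment, labels)
  tick("cluster")

  # --- photometry -------------------------------------------------------
  phot_summary <- NULL
  if (isTRUE(cfg$photometry$enabled)) {
    peaks <- c()
    for (i in seq_along(sessions)) {
      pop <- names(sessions)[i]
      sim <- simulate_photometry(sessions[[pop]]$events,
                                 default_template(pop),
                                 seed = derive_seed(cfg$seed, 2000, i))
      proc <- process_photometry(sim$recording)
      peaks[[pop]] <- proc$peak_reward_dff
    }
    phot_summary <- data.frame(population = names(peaks),
                               peak_reward_dff = unlist(peaks))
  }
  tick("photometry")

  # --- distributional TD model ------------------------------------------
  td_cfg <- td_config(gamma = cfg$td$gamma, n_states = cfg$td$n_states,
                      reward_mean = cfg$td$reward_mean,
                      reward_sd = cfg$td$reward_sd,
                      n_neurons = cfg$td$n_neurons,
                      n_training_trials = cfg$td$n_training_trials,
                      seed = derive_seed(cfg$seed, 3000))
  responses <- reward_window_responses(sessions)
  agents <- build_projection_agents(responses, td_cfg)
  td_tab <- do.call(rbind, lapply(names(agents), function(nm) {
    ev <- evaluate_agent(agents[[nm]], td_cfg, seed = derive_seed(cfg$seed, 3000))
    data.frame(agent = nm,
               mean_asymmetry = mean(agents[[nm]]$fit$asymmetry),
               mean_value = mean(agents[[nm]]$value_estimate),
               mean_mse = ev$mean_mse, bias = ev$bias)
  }))
  tick("tdmodel")

  report <- list(
    n_units = nrow(encoding_tab),
    encoding = encoding_tab,
    firing = firing_tab,
    clustering = list(assignment = assignment,
                      enrichment = enrichment$modal_fraction),
    photometry = phot_summary,
    td = td_tab,
    provenance = list(seed = cfg$seed,
                      config = unclass(cfg))
  )
  report$provenance$hash <- rlang::hash(report)
  report$timing_s <- timing

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (pop in names(sessions)) {
      write_session_events_csv(sessions[[pop]]$events,
                               file.path(cfg$out_dir, paste0("events_", pop, ".csv")))
      write_spike_trains_csv(sessions[[pop]],
                             file.path(cfg$out_dir, paste0("spikes_", pop, ".csv")))
    }
    utils::write.csv(encoding_tab, file.path(cfg$out_dir, "encoding.csv"),
                     row.names = FALSE)
    utils::write.csv(firing_tab, file.path(cfg$out_dir, "firing.csv"),
                     row.names = FALSE)
    utils::write.csv(td_tab, file.path(cfg$out_dir, "td_agents.csv"),
                     row.names = FALSE)
    write_dendrogram_newick(dend, file.path(cfg$out_dir, "dendrogram.nwk"))
    jsonlite::write_json(report[c("n_units", "provenance")],
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(report) <- "run_report"
  report
}
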