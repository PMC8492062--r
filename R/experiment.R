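CONFIG_FIELDS <- c("model", "variant", "n_somites", "duration", "seed",
                   "record_dt", "sigma_d", "sigma_p", "sigma_w", "sigma_l",
                   "sigma_w_chem", "sigma_w_gap", "overrides", "silence",
                   "block", "out_dir", "episode_threshold",
                   "crossing_threshold", "max_lag", "coil_args")

circuit_from_config <- function(cfg) {
  model <- cfg$model
  if (is.null(model)) stop("config error at 'model': a model name is required")
  n_somites <- cfg$n_somites
  overrides <- cfg$overrides
  switch(model,
    single_coiling = build_single_coiling(
      if (is.null(n_somites)) 10 else n_somites, overrides),
    double_coiling = build_double_coiling(
      if (is.null(n_somites)) 10 else n_somites, overrides),
    beat_and_glide = build_beat_and_glide(
      if (is.null(cfg$variant)) "base" else cfg$variant,
      if (is.null(n_somites)) 15 else n_somites, overrides),
    stop("config error at 'model': unknown model ", model)
  )
}

#' Run a configured experiment and write its artifacts
#'
#' The configuration is a named list (or path to a YAML file) selecting the
#' model, duration, seed, parameter overrides, noise levels, and optional
#' perturbations. The simulation is run, summarized, and written to
#' \code{out_dir}: \code{manifest.json} (full configuration and seed, enough
#' to regenerate the run bit-identically), \code{summary.json},
#' \code{episodes.csv}, \code{coil_events.csv} and the body-angle heat map
#' \code{theta.csv} (time by segment).
#'
#' @param config named list or YAML file path. Recognized fields: model
#'   (single_coiling / double_coiling / beat_and_glide), variant, n_somites,
#'   duration, seed, record_dt, sigma_d / sigma_p / sigma_w / sigma_l /
#'   sigma_w_chem / sigma_w_gap, overrides, silence (list with population,
#'   start, end), block (list with class, start, end), out_dir, and the
#'   analysis thresholds (episode_threshold, crossing_threshold, max_lag,
#'   coil_args). Unknown fields are rejected.
#' @return invisibly, a list with the simulation and its summary.
#' @export
run_experiment <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), CONFIG_FIELDS)
  if (length(unknown) > 0)
    stop("config error: unknown field(s) ", paste(unknown, collapse = ", "))
  if (is.null(config$duration))
    stop("config error at 'duration': required")
  num_or <- function(x, default) if (is.null(x)) default else x

  seed <- num_or(config$seed, 1L)
  set.seed(seed)
  circuit <- circuit_from_config(config)
  circuit <- randomize_circuit(circuit,
                               sigma_w = num_or(config$sigma_w, 0),
                               sigma_w_chem = num_or(config$sigma_w_chem, 0),
                               sigma_w_gap = num_or(config$sigma_w_gap, 0),
                               sigma_p = num_or(config$sigma_p, 0),
                               sigma_l = num_or(config$sigma_l, 0))
  plans <- list()
  if (!is.null(config$silence)) {
    s <- config$silence
    if (!all(s$population %in% circuit$neurons$kind))
      stop("config error at 'silence.population': unknown population ",
           s$population)
    plans <- c(plans, list(silence_population(s$population, s$start, s$end)))
  }
  if (!is.null(config$block)) {
    b <- config$block
    plans <- c(plans, list(block_transmitter(b$class, b$start, b$end)))
  }
  sim <- simulate_circuit(circuit, config$duration,
                          record_dt = num_or(config$record_dt, 1),
                          sigma_d = num_or(config$sigma_d, 0),
                          perturbations = if (length(plans)) plans else NULL,
                          record_V = FALSE)
  summ <- summarize_locomotion(
    sim,
    episode_threshold = num_or(config$episode_threshold, 0.5),
    crossing_threshold = num_or(config$crossing_threshold, 0.5),
    max_lag = num_or(config$max_lag, 10),
    coil_args = if (is.null(config$coil_args)) list() else config$coil_args)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(config = config, seed = seed,
           package_version = as.character(utils::packageVersion("zebracpg"))),
      file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(
        n_episodes = nrow(summ$episodes),
        episode_duration_mean = mean_or_na(summ$episodes$duration),
        interval_mean = mean_or_na(summ$intervals),
        tail_beat_freq_mean = mean_or_na(summ$tail_beat_freqs),
        coil_proportions = as.list(summ$coil_proportions),
        lr_crosscorr = summ$lr_crosscorr),
      file.path(config$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(summ$episodes,
                     file.path(config$out_dir, "episodes.csv"),
                     row.names = FALSE)
    utils::write.csv(summ$coil_events,
                     file.path(config$out_dir, "coil_events.csv"),
                     row.names = FALSE)
    theta <- as.data.frame(sim$theta)
    names(theta) <- paste0("segment_", seq_len(ncol(sim$theta)))
    theta <- cbind(time = sim$time, theta)
    utils::write.csv(theta, file.path(config$out_dir, "theta.csv"),
                     row.names = FALSE)
  }
  invisible(list(sim = sim, summary = summ, circuit = circuit))
}

#' Recompute the headline locomotor statistics of the three models
#'
#' Runs the base single coiling simulation, the noisy double coiling battery,
#' and the beat-and-glide battery, and returns the quantities the models are
#' judged on: coiling frequency and mean single-coil duration; double- and
#' single-coil percentages and mean double-coil duration; mean episode
#' duration, inter-episode interval and tail-beat frequency. All simulations
#' are run from scratch; sub-seeds are derived from \code{seed}.
#'
#' @param seed base integer seed.
#' @param n_double_runs,double_duration double coiling battery size (paper
#'   scale: five 100,000 ms runs).
#' @param n_bg_runs,bg_duration beat-and-glide battery size (paper scale: ten
#'   10,000 ms runs).
#' @param progress print progress messages.
#' @return list with elements \code{coiling_frequency_hz},
#'   \code{single_coil_duration_ms}, \code{double_coil_pct},
#'   \code{single_coil_pct}, \code{double_coil_duration_ms},
#'   \code{episode_duration_ms}, \code{interval_ms},
#'   \code{tail_beat_freq_hz}, plus the underlying per-run tables.
#' @export
reproduce_paper_suite <- function(seed = 1, n_double_runs = 5,
                                  double_duration = 100000,
                                  n_bg_runs = 10, bg_duration = 10000,
                                  progress = FALSE) {
  say <- function(...) if (progress) message(...)

  # --- single coiling: one deterministic 10 s run -------------------------
  say("single coiling run")
  sc <- simulate_circuit(build_single_coiling(), duration = 10000,
                         seed = seed, record_V = FALSE)
  sc_sum <- summarize_locomotion(sc)
  ev <- sc_sum$coil_events
  n_full_coils <- if (nrow(ev) > 0) sum(ev$n_coils[ev$class != "truncated"])
                  else 0
  coiling_freq <- n_full_coils / (sc$duration / 1000)
  single_dur <- mean_or_na(ev$duration[ev$class == "single" & !ev$censored])

  # --- double coiling: noisy battery --------------------------------------
  dc_events <- list()
  for (j in seq_len(n_double_runs)) {
    say("double coiling run ", j, "/", n_double_runs)
    set.seed(seed + 100L + j)
    circ <- build_double_coiling()
    circ <- randomize_circuit(circ, sigma_w = 0.05, sigma_p = 0.01)
    sim <- simulate_circuit(circ, double_duration, sigma_d = 0.5,
                            record_V = FALSE)
    s <- summarize_locomotion(sim)
    e <- s$coil_events
    if (nrow(e) > 0) e$run <- j
    dc_events[[j]] <- e
  }
  dc <- do.call(rbind, dc_events)
  double_pct <- 100 * mean(dc$class == "double")
  single_pct <- 100 * mean(dc$class == "single")
  double_dur <- mean_or_na(dc$duration[dc$class == "double" & !dc$censored])

  # --- beat-and-glide: base battery ---------------------------------------
  bg_rows <- list()
  for (j in seq_len(n_bg_runs)) {
    say("beat-and-glide run ", j, "/", n_bg_runs)
    set.seed(seed + 200L + j)
    circ <- build_beat_and_glide("base")
    sim <- simulate_circuit(circ, bg_duration, record_V = FALSE)
    s <- summarize_locomotion(sim)
    bg_rows[[j]] <- data.frame(
      run = j,
      episode_duration = mean_or_na(s$episodes$duration),
      interval = mean_or_na(s$intervals),
      tbf = mean_or_na(s$tail_beat_freqs),
      n_episodes = nrow(s$episodes))
  }
  bg <- do.call(rbind, bg_rows)

  list(
    coiling_frequency_hz = coiling_freq,
    single_coil_duration_ms = single_dur,
    double_coil_pct = double_pct,
    single_coil_pct = single_pct,
    double_coil_duration_ms = double_dur,
    episode_duration_ms = mean(bg$episode_duration, na.rm = TRUE),
    interval_ms = mean(bg$interval, na.rm = TRUE),
    tail_beat_freq_hz = mean(bg$tbf, na.rm = TRUE),
    single_coiling = sc_sum,
    double_coil_events = dc,
    beat_glide_runs = bg
  )
}
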