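#' In-silico silencing of a spinal population
#'
#' During the given epochs all synaptic and external currents to every member
#' of the population (both sides) are removed; the membrane dynamics keep
#' running on zero input, so outgoing synapses fall silent because the neurons
#' stop firing. Whether gap-junction input is included is controlled at
#' simulation time (\code{silence_includes_gap}, default yes).
#'
#' @param population population name (e.g. \code{"IC"}, \code{"V2a"}).
#' @param start,end epoch bounds (ms), or give \code{epochs} directly.
#' @param epochs two-column matrix of (start, end) rows; must be
#'   non-overlapping.
#' @return a \code{perturbation} object.
#' @export
silence_population <- function(population, start = NULL, end = NULL,
                               epochs = NULL) {
  new_perturbation("silence_population", population, start, end, epochs)
}

#' In-silico blockade of a transmitter class
#'
#' All chemical currents of the class are zero during the epochs; gap
#' junctions (and the neuromuscular junction, which is not a spinal
#' glutamatergic synapse) are unaffected.
#'
#' @param class \code{"glycinergic"} or \code{"glutamatergic"}.
#' @inheritParams silence_population
#' @export
block_transmitter <- function(class = c("glycinergic", "glutamatergic"),
                              start = NULL, end = NULL, epochs = NULL) {
  class <- match.arg(class)
  new_perturbation("block_transmitter", class, start, end, epochs)
}

new_perturbation <- function(kind, target, start, end, epochs) {
  if (is.null(epochs)) {
    if (is.null(start) || is.null(end))
      stop("give either start and end, or an epochs matrix")
    epochs <- cbind(start, end)
  }
  epochs <- matrix(as.numeric(epochs), ncol = 2)
  if (any(epochs[, 1] >= epochs[, 2]))
    stop("each epoch must have start < end")
  if (nrow(epochs) > 1) {
    o <- order(epochs[, 1])
    epochs <- epochs[o, , drop = FALSE]
    if (any(epochs[-1, 1] < epochs[-nrow(epochs), 2]))
      stop("epochs must be non-overlapping")
  }
  structure(list(kind = kind, target = target, epochs = epochs),
            class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat("Perturbation:", x$kind, "->", x$target, "\n")
  for (r in seq_len(nrow(x$epochs)))
    cat("  epoch:", x$epochs[r, 1], "-", x$epochs[r, 2], "ms\n")
  invisible(x)
}

#' Three-epoch perturbation protocol
#'
#' Runs one simulation of three equal epochs with the perturbation active only
#' in the middle epoch (intact - perturbed - restored) and summarizes the
#' locomotor output of each epoch separately.
#'
#' @param circuit a \code{spinal_circuit}.
#' @param perturbation a \code{perturbation} built with epochs omitted (the
#'   protocol assigns the middle epoch), or \code{NULL} for a control run.
#' @param epoch_ms epoch duration (ms).
#' @param seed integer seed for the run.
#' @param sigma_d drive-noise level passed to [simulate_circuit()].
#' @param ... further arguments to [summarize_locomotion()].
#' @return list with the full simulation (\code{sim}), per-epoch
#'   \code{locomotor_summary} objects (\code{epochs}), and a per-epoch
#'   statistics table (\code{stats}: mean and sd of episode duration,
#'   inter-episode interval, tail-beat frequency, and the mid-body minimum
#'   left-right cross-correlation).
#' @export
three_epoch_protocol <- function(circuit, perturbation, epoch_ms = 5000,
                                 seed = NULL, sigma_d = 0, ...) {
  duration <- 3 * epoch_ms
  plans <- NULL
  if (!is.null(perturbation)) {
    stopifnot(inherits(perturbation, "perturbation"))
    perturbation$epochs <- cbind(epoch_ms, 2 * epoch_ms)
    plans <- perturbation
  }
  sim <- simulate_circuit(circuit, duration, seed = seed, sigma_d = sigma_d,
                          perturbations = plans, record_V = FALSE)
  bounds <- list(c(200, epoch_ms), c(epoch_ms, 2 * epoch_ms),
                 c(2 * epoch_ms, 3 * epoch_ms))
  # episodes are detected once on the whole run and assigned to the epoch
  # containing their midpoint, so a bout spanning an epoch boundary is
  # counted exactly once, in the epoch holding most of it
  epochs <- lapply(bounds, function(b) {
    window_summary(sim, b[1], b[2], ...)
  })
  stats <- do.call(rbind, lapply(seq_along(epochs), function(i) {
    s <- epochs[[i]]
    data.frame(
      epoch = i,
      n_episodes = nrow(s$episodes),
      episode_duration_mean = mean_or_na(s$episodes$duration),
      episode_duration_sd = sd_or_na(s$episodes$duration),
      interval_mean = mean_or_na(s$intervals),
      interval_sd = sd_or_na(s$intervals),
      tbf_mean = mean_or_na(s$tail_beat_freqs),
      tbf_sd = sd_or_na(s$tail_beat_freqs),
      lr_crosscorr_mid = s$lr_crosscorr[ceiling(length(s$lr_crosscorr) / 2)]
    )
  }))
  list(sim = sim, epochs = epochs, stats = stats)
}

# locomotor summary restricted to a time window; episodes are detected on the
# full trace and assigned to the window holding their midpoint
window_summary <- function(sim, from, to, episode_threshold = 0.5,
                           crossing_threshold = 0.5, max_lag = 10) {
  keepall <- sim$time >= 200
  eps_all <- detect_episodes(integrated_motor_output(sim)[keepall],
                             sim$time[keepall], episode_threshold)
  mid <- (eps_all$start + eps_all$end) / 2
  eps <- eps_all[mid >= from & mid < to, , drop = FALSE]
  keep <- sim$time >= from & sim$time < to
  tt <- sim$time[keep]
  y <- tail_displacement(sim)[keep]
  tbf <- tail_beat_frequencies(y, tt, crossing_threshold)
  nsom <- ncol(sim$theta)
  left <- sim$muscle_V[keep, seq_len(nsom), drop = FALSE]
  right <- sim$muscle_V[keep, nsom + seq_len(nsom), drop = FALSE]
  xcorr <- vapply(seq_len(nsom), function(i) {
    min_lr_crosscorr(left[, i], right[, i], sim$record_dt, max_lag)
  }, numeric(1))
  structure(list(
    episodes = eps, intervals = inter_episode_intervals(eps),
    tail_beat_freqs = tbf, lr_crosscorr = xcorr,
    coil_events = data.frame(), coil_proportions = NULL,
    analyzed_ms = c(from, to), model = sim$model
  ), class = "locomotor_summary")
}

mean_or_na <- function(x) if (length(x) > 0) mean(x) else NA_real_
sd_or_na <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
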