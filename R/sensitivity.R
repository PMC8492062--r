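#' Apply Gaussian multiplicative parameter noise to a circuit
#'
#' Implements the parameter-noise battery: every affected scalar is multiplied
#' once, at initialization, by an independent Gaussian(1, sigma) draw.
#' \code{sigma_w} scales every synaptic weight (\code{sigma_w_chem} /
#' \code{sigma_w_gap} restrict to one class), \code{sigma_p} every membrane
#' parameter of every neuron, and \code{sigma_l} every projection's
#' rostrocaudal extent (target sets and delays are rebuilt from the perturbed
#' extents, rounded to whole segments). Weights and lengths clamp negative
#' draws at zero; membrane parameters stay signed. Drive noise
#' (\code{sigma_d}) is a per-time-step process and lives in
#' [simulate_circuit()]. Draws come from the current RNG state in the fixed
#' order weights, then membrane parameters, then lengths.
#'
#' @param circuit a \code{spinal_circuit}.
#' @param sigma_w,sigma_w_chem,sigma_w_gap,sigma_p,sigma_l non-negative
#'   standard deviations.
#' @return a perturbed \code{spinal_circuit}.
#' @export
randomize_circuit <- function(circuit, sigma_w = 0, sigma_w_chem = 0,
                              sigma_w_gap = 0, sigma_p = 0, sigma_l = 0) {
  stopifnot(inherits(circuit, "spinal_circuit"))

  if (sigma_l > 0) {
    info <- circuit$rule_info
    perturbable <- info$mode %in% c("neighbor_count", "segment_range",
                                    "first_n")
    factors <- list()
    for (r in seq_len(nrow(info))) {
      if (!perturbable[r]) next
      npre <- sum(circuit$neurons$kind == info$pre[r])
      factors[[info$name[r]]] <- pmax(0, stats::rnorm(npre, 1, sigma_l))
    }
    circuit <- build_circuit(circuit$meta$variant, circuit$meta$n_somites,
                             circuit$meta$overrides, length_factors = factors)
  }

  conns <- circuit$connections
  if (sigma_w > 0) {
    conns$weight <- conns$weight * pmax(0, stats::rnorm(nrow(conns), 1,
                                                        sigma_w))
  }
  if (sigma_w_chem > 0) {
    sel <- conns$kind %in% c("glut", "gly")
    conns$weight[sel] <- conns$weight[sel] *
      pmax(0, stats::rnorm(sum(sel), 1, sigma_w_chem))
  }
  if (sigma_w_gap > 0) {
    sel <- conns$kind == "gap"
    conns$weight[sel] <- conns$weight[sel] *
      pmax(0, stats::rnorm(sum(sel), 1, sigma_w_gap))
  }
  if (sigma_w > 0 || sigma_w_chem > 0 || sigma_w_gap > 0) {
    mus <- circuit$muscles
    mus$weight <- mus$weight  # neuromuscular weights follow sigma_w only
    if (sigma_w > 0)
      mus$weight <- mus$weight * pmax(0, stats::rnorm(nrow(mus), 1, sigma_w))
    circuit$muscles <- mus
  }
  circuit$connections <- conns

  if (sigma_p > 0) {
    cols <- c("a", "b", "c", "d", "Vmax", "Vr", "Vt", "k", "C")
    nrm <- as.matrix(circuit$neurons[, cols])
    nrm <- nrm * matrix(stats::rnorm(length(nrm), 1, sigma_p), nrow(nrm))
    circuit$neurons[, cols] <- nrm
  }
  circuit
}

#' Run a parameter-noise sensitivity battery
#'
#' For each value of one noise parameter, runs \code{n_runs} independent
#' simulations (fresh seeds, fresh noise draws) and collects the locomotor
#' metrics of each run: for the coiling models the coiling frequency (full
#' coils per second) and proportion of full coils; for the swimming models
#' episode duration, inter-episode interval, tail-beat frequency, and the
#' mid-body minimum left-right cross-correlation.
#'
#' @param factory a function returning a fresh \code{spinal_circuit} (e.g.
#'   \code{build_single_coiling}).
#' @param sigma_name one of \code{"sigma_d"}, \code{"sigma_l"},
#'   \code{"sigma_p"}, \code{"sigma_w"}, \code{"sigma_w_chem"},
#'   \code{"sigma_w_gap"}. Only this parameter is varied; the others stay 0.
#' @param sigma_values numeric grid of noise levels.
#' @param n_runs simulations per level.
#' @param duration run length (ms).
#' @param base_seed integer; run \code{j} of level \code{i} uses seed
#'   \code{base_seed + 1000 * (i - 1) + j}.
#' @param coil_args passed to [classify_coils()].
#' @return data frame, one row per run: sigma name and value, seed, and the
#'   metrics (coiling frequency and coil-class counts, or episode statistics).
#' @export
run_battery <- function(factory, sigma_name, sigma_values, n_runs = 10,
                        duration = 20000, base_seed = 1, coil_args = list()) {
  sigma_name <- match.arg(sigma_name,
                          c("sigma_d", "sigma_l", "sigma_p", "sigma_w",
                            "sigma_w_chem", "sigma_w_gap"))
  rows <- list()
  for (i in seq_along(sigma_values)) {
    sv <- sigma_values[i]
    for (j in seq_len(n_runs)) {
      seed <- base_seed + 1000L * (i - 1L) + j
      set.seed(seed)
      circ <- factory()
      rand_args <- list(circuit = circ)
      if (sigma_name != "sigma_d") rand_args[[sigma_name]] <- sv
      circ <- do.call(randomize_circuit, rand_args)
      sim <- simulate_circuit(circ, duration,
                              sigma_d = if (sigma_name == "sigma_d") sv else 0,
                              record_V = FALSE)
      s <- summarize_locomotion(sim, coil_args = coil_args)
      analyzed_s <- (duration - 200) / 1000
      ev <- s$coil_events
      nfull <- if (nrow(ev) > 0) sum(ev$n_coils[ev$class != "truncated"])
               else 0
      rows[[length(rows) + 1L]] <- data.frame(
        sigma = sigma_name, value = sv, seed = seed,
        coil_freq = nfull / analyzed_s,
        prop_full = if (nrow(ev) > 0) {
          sum(ev$n_coils[ev$class != "truncated"]) /
            (sum(ev$n_coils[ev$class != "truncated"]) +
               sum(ev$class == "truncated"))
        } else NA_real_,
        n_single = sum(ev$class == "single"),
        n_double = sum(ev$class == "double"),
        n_multiple = sum(ev$class == "multiple"),
        n_truncated = sum(ev$class == "truncated"),
        episode_duration = mean_or_na(s$episodes$duration),
        interval = mean_or_na(s$intervals),
        tbf = mean_or_na(s$tail_beat_freqs),
        lr_crosscorr =
          s$lr_crosscorr[ceiling(length(s$lr_crosscorr) / 2)]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
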