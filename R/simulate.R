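#' Simulate a spinal circuit model
#'
#' Integrates the full network (neurons, muscle cells, body segments) with
#' forward Euler at the circuit's time step (0.1 ms). Gap junctions inject the
#' delayed presynaptic potential times the coupling weight; chemical synapses
#' are dual-exponential kernels triggered when the delayed presynaptic
#' potential rises through the release threshold (-15 mV), with the kernel
#' clock reset at each new crossing. All chemical currents are off during the
#' first 50 ms so initial conditions can dissipate. Motoneuron firing drives
#' one muscle cell per somite and side; the right-left muscle difference
#' forces a chain of uncoupled, critically damped pendulums whose angles are
#' the local body curvature.
#'
#' @param circuit a \code{spinal_circuit} from one of the model factories.
#' @param duration simulation length (ms).
#' @param seed optional integer; when given, \code{set.seed(seed)} is called so
#'   the run is fully reproducible. When \code{NULL} the current RNG state is
#'   used (as in sensitivity batteries that randomize the model first).
#' @param record_dt recording interval (ms) for traces; spike times are always
#'   exact. Must be a multiple of the integration step.
#' @param sigma_d standard deviation of the per-time-step Gaussian(1, sigma_d)
#'   scaling of the tonic command amplitude.
#' @param perturbations a single perturbation (see [silence_population()],
#'   [block_transmitter()]) or a list of them.
#' @param record_V record membrane-potential traces (set \code{FALSE} in long
#'   batteries to save memory; muscle and body traces are always kept).
#' @param silence_includes_gap whether silencing removes gap-junction input as
#'   well as chemical and drive currents (default \code{TRUE}: "all synaptic
#'   and external currents").
#' @param gap_form gap-junction current convention. The default
#'   \code{"difference"} is the ohmic form
#'   \eqn{G\,(V_{pre}(t - delay) - V_{post})}, the only convention under
#'   which a resting network is a stable fixed point and activity both
#'   propagates and terminates. \code{"rest_referenced"} injects the
#'   presynaptic deviation from rest, \eqn{G\,(V_{pre} - V_{r,pre})} (no
#'   restoring load; chains self-sustain), and \code{"printed"} the literal
#'   absolute-potential product \eqn{G\,V_{pre}} (tonically hyperpolarizes a
#'   resting network); both kept for comparison.
#' @return a \code{spinal_sim} object: recorded time grid, membrane traces,
#'   exact spike times, muscle potentials and input currents, and body angles.
#' @export
#' @examples
#' circ <- build_single_coiling()
#' sim <- simulate_circuit(circ, duration = 1000, seed = 1)
#' print(sim)
simulate_circuit <- function(circuit, duration, seed = NULL, record_dt = 1,
                             sigma_d = 0, perturbations = NULL,
                             record_V = TRUE, silence_includes_gap = TRUE,
                             gap_form = c("difference", "rest_referenced",
                                          "printed")) {
  gap_form <- match.arg(gap_form)
  stopifnot(inherits(circuit, "spinal_circuit"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  cst <- circuit$constants
  dt <- cst$dt
  stride <- round(record_dt / dt)
  if (stride < 1 || abs(stride * dt - record_dt) > 1e-9)
    stop("record_dt must be a positive multiple of the integration step")

  nrm <- as.matrix(circuit$neurons[, c("a", "b", "c", "d", "Vmax", "Vr",
                                       "Vt", "k", "C")])
  conns <- circuit$connections
  type_code <- match(conns$kind, c("gap", "glut", "gly")) - 1L
  if (anyNA(type_code)) stop("unknown connection kind in circuit")
  delay_steps <- as.integer(round(conns$delay / dt))

  pw <- resolve_perturbations(circuit, perturbations, duration)

  raw <- .engine_run(
    nrm,
    circuit$neurons$I_drive, circuit$neurons$drive_onset,
    as.integer(conns$pre), as.integer(conns$post), type_code,
    conns$weight, delay_steps,
    as.integer(circuit$muscles$mn_id), circuit$muscles$weight,
    circuit$muscle$R, circuit$muscle$C,
    circuit$body$zeta, circuit$body$omega0, circuit$body$gain,
    cst$E_glut, cst$E_gly, cst$tau_r, cst$tau_f, cst$V_thr,
    dt, duration, cst$chem_off_ms,
    sigma_d, stride, record_V,
    pw$silence, pw$block,
    silence_includes_gap,
    match(gap_form, c("printed", "difference", "rest_referenced")) - 1L,
    nm_Vref = mean(circuit$neurons$Vr[circuit$neurons$kind == "MN"])
  )

  labels <- paste0(circuit$neurons$kind, "_",
                   substr(circuit$neurons$side, 1, 1),
                   circuit$neurons$index)
  if (record_V) colnames(raw$V) <- labels
  names(raw$spikes) <- labels
  mlab <- paste0("M_", substr(circuit$muscles$side, 1, 1),
                 circuit$muscles$cell)
  colnames(raw$muscle_V) <- mlab
  colnames(raw$muscle_I) <- mlab

  structure(list(
    time = raw$time,
    V = if (record_V) raw$V else NULL,
    spikes = raw$spikes,
    muscle_V = raw$muscle_V,
    muscle_I = raw$muscle_I,
    theta = raw$theta,
    neurons = circuit$neurons[, c("id", "kind", "side", "index", "segment")],
    model = circuit$name,
    n_somites = circuit$n_somites,
    body = circuit$body,
    muscle = circuit$muscle,
    duration = duration,
    record_dt = record_dt,
    seed = seed,
    sigma_d = sigma_d
  ), class = "spinal_sim")
}

resolve_perturbations <- function(circuit, perturbations, duration) {
  empty <- matrix(numeric(0), ncol = 3)
  if (is.null(perturbations))
    return(list(silence = empty, block = empty))
  if (inherits(perturbations, "perturbation"))
    perturbations <- list(perturbations)
  sil <- list(); blk <- list()
  for (p in perturbations) {
    stopifnot(inherits(p, "perturbation"))
    ep <- p$epochs
    if (any(ep[, 1] >= ep[, 2]))
      stop("perturbation epochs must have start < end")
    if (any(ep[, 1] < 0) || any(ep[, 2] > duration))
      stop("perturbation epochs must lie within the simulation duration")
    if (identical(p$kind, "silence_population")) {
      ids <- circuit$neurons$id[circuit$neurons$kind == p$target]
      if (length(ids) == 0L)
        stop("unknown population in silencing plan: ", p$target)
      for (r in seq_len(nrow(ep)))
        sil[[length(sil) + 1L]] <- cbind(ids, ep[r, 1], ep[r, 2])
    } else {
      code <- if (identical(p$target, "glutamatergic")) 1 else 2
      for (r in seq_len(nrow(ep)))
        blk[[length(blk) + 1L]] <- cbind(code, ep[r, 1], ep[r, 2])
    }
  }
  list(
    silence = if (length(sil)) do.call(rbind, sil) else empty,
    block = if (length(blk)) do.call(rbind, blk) else empty
  )
}

#' @export
print.spinal_sim <- function(x, ...) {
  cat("Spinal circuit simulation:", x$model, "\n")
  cat("  duration:", x$duration, "ms, recorded every", x$record_dt, "ms\n")
  nsp <- sum(vapply(x$spikes, length, 1L))
  cat("  neurons:", nrow(x$neurons), " total spikes:", nsp, "\n")
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' @export
plot.spinal_sim <- function(x, what = c("theta", "muscle", "V"),
                            neurons = NULL, ...) {
  what <- match.arg(what)
  if (what == "theta") {
    graphics::image(x = x$time, y = seq_len(ncol(x$theta)), z = x$theta,
                    xlab = "time (ms)", ylab = "body segment",
                    main = "local body angle (rad)",
                    col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  } else if (what == "muscle") {
    graphics::matplot(x$time, x$muscle_V, type = "l", lty = 1,
                      xlab = "time (ms)", ylab = "muscle potential", ...)
  } else {
    if (is.null(x$V)) stop("membrane traces were not recorded")
    sel <- if (is.null(neurons)) seq_len(min(6, ncol(x$V))) else neurons
    graphics::matplot(x$time, x$V[, sel, drop = FALSE], type = "l", lty = 1,
                      xlab = "time (ms)", ylab = "V (mV)", ...)
  }
  invisible(x)
}

#' Spike times of a population
#'
#' @param sim a \code{spinal_sim}.
#' @param kind population name; \code{NULL} for all.
#' @param side \code{"left"}, \code{"right"} or \code{NULL} for both.
#' @return named list of numeric spike-time vectors (ms).
#' @export
spike_times <- function(sim, kind = NULL, side = NULL) {
  keep <- rep(TRUE, nrow(sim$neurons))
  if (!is.null(kind)) keep <- keep & sim$neurons$kind %in% kind
  if (!is.null(side)) keep <- keep & sim$neurons$side %in% side
  sim$spikes[keep]
}
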