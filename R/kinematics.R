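#' Detect locomotor episodes in the integrated motor output
#'
#' Episodes are maximal intervals where the trace is at or above the
#' threshold; inter-episode intervals are the gaps between consecutive
#' episodes.
#'
#' @param trace integrated motor output on a uniform grid.
#' @param time matching time vector (ms).
#' @param threshold detection threshold (arbitrary units of the trace).
#' @return data frame with columns start, end, duration (ms); zero rows when
#'   nothing crosses the threshold.
#' @export
detect_episodes <- function(trace, time, threshold = 0.5) {
  stopifnot(length(trace) == length(time))
  above <- trace >= threshold
  if (!any(above)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  out <- data.frame(start = time[starts[on]], end = time[ends[on]])
  out$duration <- out$end - out$start
  out[out$duration > 0, , drop = FALSE]
}

#' Inter-episode intervals
#' @param episodes data frame from [detect_episodes()].
#' @return numeric vector of gaps between consecutive episodes (ms).
#' @export
inter_episode_intervals <- function(episodes) {
  if (nrow(episodes) < 2) return(numeric(0))
  episodes$start[-1] - episodes$end[-nrow(episodes)]
}

#' Instantaneous tail-beat frequencies from midline crossings
#'
#' Detects when the tail-displacement signal crosses from one side of the body
#' axis to the other (a side is reached when |signal| exceeds the crossing
#' threshold). The reciprocal of the interval between consecutive
#' same-direction crossings gives the instantaneous frequency; intervals
#' longer than \code{max_interval} are between episodes and discarded.
#'
#' @param y tail displacement on a uniform grid.
#' @param time matching time vector (ms).
#' @param threshold crossing threshold (same units as \code{y}).
#' @param max_interval longest within-episode beat interval (ms).
#' @return numeric vector of frequencies (Hz); empty when fewer than two
#'   same-direction crossings occur.
#' @export
tail_beat_frequencies <- function(y, time, threshold = 0.5,
                                  max_interval = 100) {
  stopifnot(length(y) == length(time))
  side <- integer(length(y))
  side[y >= threshold] <- 1L
  side[y <= -threshold] <- -1L
  cross_t <- numeric(0)
  cross_dir <- integer(0)
  cur <- 0L
  for (i in seq_along(side)) {
    s <- side[i]
    if (s != 0L && s != cur) {
      if (cur != 0L) {
        cross_t <- c(cross_t, time[i])
        cross_dir <- c(cross_dir, s)
      }
      cur <- s
    }
  }
  if (length(cross_t) < 2) return(numeric(0))
  freqs <- numeric(0)
  for (dir in c(-1L, 1L)) {
    tt <- cross_t[cross_dir == dir]
    if (length(tt) >= 2) {
      iv <- diff(tt)
      iv <- iv[iv <= max_interval]
      freqs <- c(freqs, 1000 / iv)
    }
  }
  freqs
}

#' Minimum left-right cross-correlation coefficient
#'
#' Normalized (non-mean-subtracted) cross-correlation of the left and right
#' muscle traces of a somite over a window of lags; the minimum coefficient
#' estimates left-right alternation (0 = out-of-phase alternation, 1 =
#' in-phase synchrony).
#'
#' @param VL,VR left and right muscle traces on a shared uniform grid.
#' @param record_dt sampling interval (ms).
#' @param max_lag lag window half-width (ms); the swimming analyses use 10 ms,
#'   20 ms is the alternative documented window.
#' @return the minimum coefficient over lags, or \code{NA} when either trace
#'   has zero energy (only one side active).
#' @export
min_lr_crosscorr <- function(VL, VR, record_dt = 1, max_lag = 10) {
  stopifnot(length(VL) == length(VR))
  eL <- sum(VL^2); eR <- sum(VR^2)
  if (eL == 0 || eR == 0) return(NA_real_)
  maxk <- round(max_lag / record_dt)
  n <- length(VL)
  denom <- sqrt(eL * eR)
  cc <- vapply(-maxk:maxk, function(k) {
    if (k >= 0) {
      sum(VL[seq_len(n - k)] * VR[seq_len(n - k) + k])
    } else {
      sum(VR[seq_len(n + k)] * VL[seq_len(n + k) - k])
    }
  }, numeric(1))
  min(cc / denom)
}

#' Phase delay between two traces
#'
#' The reference period is the lag of the autocorrelation peak of the
#' reference trace (or the supplied override, used in the coiling models where
#' the inter-event period is not the meaningful cycle); the delay is the lag of
#' the cross-correlation peak, and the phase is \eqn{2\pi\,delay/period} with
#' sign preserved (negative = reference precedes).
#'
#' @param ref,test traces on a shared uniform grid.
#' @param record_dt sampling interval (ms).
#' @param period_override reference cycle period (ms); \code{NULL} to estimate
#'   it from the autocorrelation.
#' @return phase in radians, or \code{NA} when no autocorrelation peak exists
#'   and no override is given.
#' @export
phase_delay <- function(ref, test, record_dt = 1, period_override = NULL) {
  stopifnot(length(ref) == length(test))
  refc <- ref - mean(ref)
  testc <- test - mean(test)
  n <- length(refc)
  if (is.null(period_override)) {
    maxlag <- floor(n / 2)
    ac <- vapply(seq_len(maxlag), function(k) {
      sum(refc[seq_len(n - k)] * refc[seq_len(n - k) + k])
    }, numeric(1))
    pk <- local_corr_peak(ac)
    if (is.na(pk)) return(NA_real_)
    period <- pk * record_dt
  } else {
    period <- period_override
  }
  maxk <- min(n - 2, max(1, round(period / record_dt)))
  lags <- -maxk:maxk
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(refc[seq_len(n - k)] * testc[seq_len(n - k) + k])
    else sum(testc[seq_len(n + k)] * refc[seq_len(n + k) - k])
  }, numeric(1))
  delay <- lags[which.max(cc)] * record_dt
  2 * pi * delay / period
}

# first local maximum of a positive-lag correlation profile that is a true
# peak (higher than both neighbours and positive)
local_corr_peak <- function(ac) {
  n <- length(ac)
  if (n < 3) return(NA_integer_)
  for (k in 2:(n - 1)) {
    if (ac[k] > 0 && ac[k] >= ac[k - 1] && ac[k] > ac[k + 1]) return(k)
  }
  NA_integer_
}

#' Detect and classify coiling events from the body-angle field
#'
#' A coil candidate is a maximal interval during which the body angle on one
#' side exceeds the amplitude threshold in at least one segment. A candidate
#' is a full coil when the bend reaches at least \code{caudal_fraction} of the
#' body (fraction of segments exceeding the threshold at some point during the
#' event), otherwise it is truncated (a partial rostral contraction).
#' Consecutive opposite-side full coils whose onsets are within
#' \code{pairing_window} chain into double (2) or multiple (3 or more) coiling
#' events; unchained full coils are single coils.
#'
#' @param theta matrix of body angles, rows = recorded samples, columns =
#'   segments (positive = rightward curvature).
#' @param time matching time vector (ms).
#' @param amplitude_threshold rad; calibration constant, fixed across all
#'   models and conditions.
#' @param caudal_fraction minimum body fraction for a full coil.
#' @param pairing_window maximal onset-to-onset gap chaining successive
#'   opposite-side coils (ms).
#' @param merge_gap same-side suprathreshold intervals separated by less than
#'   this (ms) are merged into one coil candidate (suppresses threshold
#'   flicker at coil onset).
#' @param min_duration candidates shorter than this (ms) are discarded.
#' @param start_at discard activity before this time (ms).
#' @return list with \code{coils} (one row per side-specific coil: side,
#'   onset, offset, duration, peak, reach, full), \code{events} (one row per
#'   classified event: class, onset, offset, duration, n_coils) and
#'   \code{proportions} (named vector over single/double/multiple/truncated).
#' @export
classify_coils <- function(theta, time, amplitude_threshold = 0.2,
                           caudal_fraction = 2 / 3, pairing_window = 1000,
                           merge_gap = 100, min_duration = 20,
                           start_at = 200) {
  keep <- time >= start_at
  theta <- theta[keep, , drop = FALSE]
  time <- time[keep]
  coils <- rbind(
    side_coils(theta, time, amplitude_threshold, "right", merge_gap,
               min_duration),
    side_coils(-theta, time, amplitude_threshold, "left", merge_gap,
               min_duration)
  )
  if (nrow(coils) == 0) {
    return(list(coils = coils,
                events = data.frame(class = character(0), onset = numeric(0),
                                    offset = numeric(0), duration = numeric(0),
                                    n_coils = integer(0)),
                proportions = c(single = NA_real_, double = NA_real_,
                                multiple = NA_real_, truncated = NA_real_)))
  }
  coils <- coils[order(coils$onset), , drop = FALSE]
  coils$full <- coils$reach >= caudal_fraction
  rownames(coils) <- NULL

  # chain consecutive opposite-side full coils
  events <- list()
  i <- 1
  nfull <- which(coils$full)
  used <- rep(FALSE, nrow(coils))
  for (i in seq_len(nrow(coils))) {
    if (used[i]) next
    used[i] <- TRUE
    if (!coils$full[i]) {
      events[[length(events) + 1L]] <- data.frame(
        class = "truncated", onset = coils$onset[i], offset = coils$offset[i],
        duration = coils$offset[i] - coils$onset[i], n_coils = 1L)
      next
    }
    chain <- i
    repeat {
      last <- chain[length(chain)]
      nxt <- which(!used & coils$full &
                   coils$side != coils$side[last] &
                   coils$onset > coils$onset[last] &
                   coils$onset - coils$onset[last] <= pairing_window)
      if (length(nxt) == 0) break
      nxt <- nxt[1]
      used[nxt] <- TRUE
      chain <- c(chain, nxt)
    }
    cls <- if (length(chain) == 1) "single"
           else if (length(chain) == 2) "double" else "multiple"
    events[[length(events) + 1L]] <- data.frame(
      class = cls, onset = coils$onset[chain[1]],
      offset = coils$offset[chain[length(chain)]],
      duration = coils$offset[chain[length(chain)]] - coils$onset[chain[1]],
      n_coils = length(chain))
  }
  events <- do.call(rbind, events)
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  # an event still above threshold at the end of the record has an unknown
  # duration; flag it so duration averages can exclude it
  events$censored <- events$offset >= time[length(time)] - 1e-9
  tab <- table(factor(events$class,
                      levels = c("single", "double", "multiple", "truncated")))
  list(coils = coils, events = events,
       proportions = stats::setNames(as.vector(tab) / nrow(events),
                                     names(tab)))
}

side_coils <- function(th, time, thr, side, merge_gap = 100,
                       min_duration = 20) {
  sig <- apply(th, 1, max)
  above <- sig >= thr
  if (!any(above)) {
    return(data.frame(side = character(0), onset = numeric(0),
                      offset = numeric(0), duration = numeric(0),
                      peak = numeric(0), reach = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  ivl <- cbind(starts[on], ends[on])
  # merge suprathreshold runs separated by brief dips
  if (nrow(ivl) > 1) {
    merged <- list(ivl[1, ])
    for (j in 2:nrow(ivl)) {
      prev <- merged[[length(merged)]]
      if (time[ivl[j, 1]] - time[prev[2]] <= merge_gap) {
        merged[[length(merged)]] <- c(prev[1], ivl[j, 2])
      } else {
        merged[[length(merged) + 1L]] <- ivl[j, ]
      }
    }
    ivl <- do.call(rbind, merged)
  }
  out <- lapply(seq_len(nrow(ivl)), function(j) {
    idx <- ivl[j, 1]:ivl[j, 2]
    block <- th[idx, , drop = FALSE]
    data.frame(side = side, onset = time[ivl[j, 1]], offset = time[ivl[j, 2]],
               duration = time[ivl[j, 2]] - time[ivl[j, 1]],
               peak = max(block),
               reach = mean(apply(block, 2, max) >= thr))
  })
  out <- do.call(rbind, out)
  out[out$duration >= min_duration, , drop = FALSE]
}

#' Summarize the locomotor output of a simulation
#'
#' Computes episodes, inter-episode intervals, instantaneous tail-beat
#' frequencies, per-somite minimum left-right cross-correlation, and (for
#' coiling models) classified coil events. The first \code{start_at}
#' milliseconds are excluded from all analyses.
#'
#' @param sim a \code{spinal_sim}.
#' @param episode_threshold threshold on the integrated motor output.
#' @param crossing_threshold tail-crossing threshold (a.d.u.).
#' @param max_lag lag window for cross-correlation (ms).
#' @param coil_args list of arguments passed to [classify_coils()].
#' @param start_at analysis start (ms).
#' @return a \code{locomotor_summary} list.
#' @export
summarize_locomotion <- function(sim, episode_threshold = 0.5,
                                 crossing_threshold = 0.5, max_lag = 10,
                                 coil_args = list(), start_at = 200) {
  keep <- sim$time >= start_at
  tt <- sim$time[keep]
  out <- integrated_motor_output(sim)[keep]
  eps <- detect_episodes(out, tt, episode_threshold)
  y <- tail_displacement(sim)[keep]
  tbf <- tail_beat_frequencies(y, tt, crossing_threshold)
  nsom <- ncol(sim$theta)
  left <- sim$muscle_V[keep, seq_len(nsom), drop = FALSE]
  right <- sim$muscle_V[keep, nsom + seq_len(nsom), drop = FALSE]
  xcorr <- vapply(seq_len(nsom), function(i) {
    min_lr_crosscorr(left[, i], right[, i], sim$record_dt, max_lag)
  }, numeric(1))
  coils <- do.call(classify_coils,
                   c(list(theta = sim$theta, time = sim$time,
                          start_at = start_at), coil_args))
  structure(list(
    episodes = eps,
    intervals = inter_episode_intervals(eps),
    tail_beat_freqs = tbf,
    lr_crosscorr = xcorr,
    coil_events = coils$events,
    coil_proportions = coils$proportions,
    analyzed_ms = c(start_at, max(sim$time)),
    model = sim$model
  ), class = "locomotor_summary")
}

#' @export
print.locomotor_summary <- function(x, ...) {
  cat("Locomotor summary (", x$model, ", ",
      x$analyzed_ms[1], "-", x$analyzed_ms[2], " ms)\n", sep = "")
  cat("  episodes:", nrow(x$episodes))
  if (nrow(x$episodes) > 0)
    cat(", mean duration", round(mean(x$episodes$duration), 1), "ms")
  if (length(x$intervals) > 0)
    cat(", mean interval", round(mean(x$intervals), 1), "ms")
  cat("\n")
  if (length(x$tail_beat_freqs) > 0)
    cat("  tail-beat frequency:", round(mean(x$tail_beat_freqs), 1),
        "Hz (mean of", length(x$tail_beat_freqs), "beats)\n")
  if (nrow(x$coil_events) > 0) {
    cat("  coil events:", nrow(x$coil_events), "(",
        paste(names(x$coil_proportions),
              round(100 * x$coil_proportions), sep = "=", collapse = "% "),
        "%)\n")
  }
  if (any(is.finite(x$lr_crosscorr)))
    cat("  min left-right cross-correlation (mid-body):",
        round(x$lr_crosscorr[ceiling(length(x$lr_crosscorr) / 2)], 3), "\n")
  invisible(x)
}
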