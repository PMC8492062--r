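#' One Euler step of a muscle cell
#'
#' Muscle cells are passive RC circuits, \eqn{V' = -V/(RC) + I_{syn}/C},
#' expressed relative to the muscle resting potential. With constant input I
#' the fixed point is \eqn{V = I R}.
#'
#' @param V muscle potential.
#' @param Isyn input current from the somite's motoneuron.
#' @param R,C membrane resistance and capacitance (positive).
#' @param dt time step (ms).
#' @return updated potential.
#' @export
muscle_step <- function(V, Isyn, R, C, dt = 0.1) {
  stopifnot(R > 0, C > 0, dt > 0)
  V + dt * (-V / (R * C) + Isyn / C)
}

#' One Euler step of a body-segment pendulum
#'
#' Each segment is an uncoupled damped pendulum,
#' \eqn{\theta'' + 2\zeta\omega_0\theta' + \omega_0^2\theta = g (V_R - V_L)},
#' forced by the right-left difference of its muscle-cell potentials. Positive
#' theta is rightward curvature.
#'
#' @param theta,dtheta angle (rad) and angular velocity (rad/ms).
#' @param VR,VL right and left muscle potentials of the segment.
#' @param zeta damping ratio.
#' @param omega0 natural frequency (rad/ms).
#' @param gain forcing gain.
#' @param dt time step (ms).
#' @return list with updated \code{theta} and \code{dtheta}.
#' @export
pendulum_step <- function(theta, dtheta, VR, VL, zeta, omega0, gain,
                          dt = 0.1) {
  F <- gain * (VR - VL)
  theta1 <- theta + dt * dtheta
  dtheta1 <- dtheta + dt * (F - 2 * zeta * omega0 * dtheta -
                            omega0^2 * theta)
  list(theta = theta1, dtheta = dtheta1)
}

#' Body midline coordinates from segment angles
#'
#' Chains the segments from the rostral origin (0, 0):
#' \eqn{x_i = x_{i-1} + l\cos\theta_i}, \eqn{y_i = y_{i-1} - l\sin\theta_i},
#' so a straight body (all angles zero) lies along the x axis and positive
#' angles (rightward curvature) bend the midline toward negative y.
#'
#' @param theta numeric vector of segment angles (rad).
#' @param l segment length (a.d.u.).
#' @return matrix with \code{length(theta) + 1} rows and columns x, y.
#' @export
compute_midline <- function(theta, l = 1.6) {
  stopifnot(all(is.finite(theta)))
  x <- c(0, cumsum(l * cos(theta)))
  y <- c(0, cumsum(-l * sin(theta)))
  cbind(x = x, y = y)
}

#' Lateral displacement of the most caudal body point
#'
#' The tail-crossing signal used for tail-beat detection: the y coordinate of
#' the last midline vertex, at every recorded sample.
#'
#' @param sim a \code{spinal_sim}.
#' @return numeric vector over the recorded time grid (a.d.u.; positive = left
#'   of the body axis under the midline sign convention).
#' @export
tail_displacement <- function(sim) {
  l <- sim$body$segment_length
  -l * rowSums(sin(sim$theta))
}

#' Integrated motor output
#'
#' The sum of the muscle potentials of all cells on both sides, convolved with
#' a unit-amplitude 50 ms square wave (a centered moving sum over the
#' convolution window). This is the trace on which swim episodes are detected.
#'
#' @param sim a \code{spinal_sim}, or a numeric matrix of muscle traces (all
#'   cells as columns) if \code{record_dt} is supplied.
#' @param width boxcar width (ms).
#' @param record_dt sampling interval of \code{sim} when a bare matrix is
#'   given.
#' @return numeric vector over the recorded time grid.
#' @export
integrated_motor_output <- function(sim, width = 50, record_dt = NULL) {
  if (inherits(sim, "spinal_sim")) {
    m <- sim$muscle_V
    record_dt <- sim$record_dt
  } else {
    m <- as.matrix(sim)
    if (is.null(record_dt)) stop("record_dt required for a bare matrix")
  }
  total <- rowSums(m)
  k <- max(1L, round(width / record_dt))
  out <- stats::filter(total, rep(1, k), method = "convolution", sides = 2)
  out[is.na(out)] <- 0
  as.numeric(out)
}
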