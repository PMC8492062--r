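#' Membrane-potential derivatives of the single-compartment spiking model
#'
#' Subthreshold dynamics of every neuron in the circuit models:
#' \deqn{C V' = k (V - V_r)(V - V_t) - u + I_{syn}}
#' \deqn{u' = a (b (V - V_r) - u)}
#' where \code{u} is the recovery variable and \code{Isyn} the summed synaptic,
#' gap-junction and drive current.
#'
#' @param V membrane potential (mV).
#' @param u recovery variable.
#' @param params named numeric vector from [izhikevich_params()].
#' @param Isyn input current.
#' @return list with elements \code{dV} and \code{du} (per ms).
#' @export
#' @examples
#' p <- izhikevich_params("MN", "single_coiling")
#' neuron_derivatives(p[["Vr"]], 0, p, 0)  # rest is a fixed point
neuron_derivatives <- function(V, u, params, Isyn) {
  if (!all(is.finite(c(V, u, Isyn))))
    stop("non-finite neuron state or input: numerical blow-up")
  p <- params
  dV <- (p[["k"]] * (V - p[["Vr"]]) * (V - p[["Vt"]]) - u + Isyn) / p[["C"]]
  du <- p[["a"]] * (p[["b"]] * (V - p[["Vr"]]) - u)
  list(dV = unname(dV), du = unname(du))
}

#' One forward-Euler step of a neuron, with the post-spike reset rule
#'
#' Advances (V, u) by \code{dt} using forward Euler; if the updated V reaches
#' the spike peak \code{Vmax} the neuron is reset (\code{V <- c},
#' \code{u <- u + d}) and a spike is flagged. The returned \code{V_trace} holds
#' the value clamped at \code{Vmax} at the spike step, matching the stored
#' traces of full simulations.
#'
#' @inheritParams neuron_derivatives
#' @param dt time step (ms), must be positive.
#' @return list with \code{V}, \code{u}, \code{spike} (logical), \code{V_trace}.
#' @export
euler_step <- function(V, u, params, Isyn, dt = 0.1) {
  stopifnot(dt > 0)
  d <- neuron_derivatives(V, u, params, Isyn)
  V1 <- V + dt * d$dV
  u1 <- u + dt * d$du
  if (V1 >= params[["Vmax"]]) {
    list(V = unname(params[["c"]]), u = unname(u1 + params[["d"]]),
         spike = TRUE, V_trace = unname(params[["Vmax"]]))
  } else {
    list(V = unname(V1), u = unname(u1), spike = FALSE, V_trace = unname(V1))
  }
}

#' Build the specification of one population of spinal neurons
#'
#' Fills positions and membrane parameters from the variant's parameter sheet.
#' Chain populations occupy one neuron per model somite at
#' \code{x = offset + 1.6 n} (a.d.u., \code{n = 0..count-1}); the IC pacemaker
#' kernel sits at the rostral position x = 1. The right side is \code{y = +1},
#' the left side \code{y = -1}.
#'
#' @param kind population name.
#' @param variant model variant name.
#' @param side \code{"left"} or \code{"right"}.
#' @param count number of neurons; defaults to the sheet value.
#' @return data frame with one row per neuron: kind, side, index, segment
#'   (0 for the IC kernel), x, y, the nine membrane parameters, drive amplitude
#'   and drive onset (ms).
#' @export
make_population <- function(kind, variant, side = c("left", "right"),
                            count = NULL) {
  side <- match.arg(side)
  sheet <- model_param_sheet(variant)
  pop <- sheet$populations[[kind]]
  if (is.null(pop))
    stop("unknown (population, variant) pair: ", kind, ", ", variant)
  if (is.null(count)) count <- pop$count
  stopifnot(count >= 1)
  make_population_from_sheet(sheet, kind, side, count)
}

# V1s start at segment 2; every other chain population at segment 1.
segment_offset <- function(kind) if (identical(kind, "V1")) 1L else 0L
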