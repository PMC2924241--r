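#' Neuron parameter presets
#'
#' Parameters of the two-variable simple spiking-neuron model
#' \deqn{v' = 0.04 v^2 + 5 v + 140 - u + I, \qquad u' = a (b v - u),}
#' with the after-spike resetting \eqn{v \leftarrow c}, \eqn{u \leftarrow u + d}
#' applied whenever \eqn{v} reaches the spike-peak cutoff of +30 mV.
#' Two immutable presets are provided: \code{"RS"} (regular spiking, used for
#' excitatory pyramidal neurons) and \code{"FS"} (fast spiking, used for
#' GABAergic inhibitory interneurons).
#'
#' @param type Either \code{"RS"} or \code{"FS"}.
#' @return A list with components \code{a} (recovery time scale, 1/ms),
#'   \code{b} (recovery sensitivity), \code{c} (post-spike membrane reset, mV)
#'   and \code{d} (post-spike recovery increment).
#' @examples
#' neuron_params("RS")
#' @export
neuron_params <- function(type = c("RS", "FS")) {
  type <- match.arg(type)
  if (type == "RS") list(a = 0.02, b = 0.2, c = -65, d = 8)
  else              list(a = 0.1,  b = 0.2, c = -65, d = 2)
}

#' Resting state of a neuron
#'
#' The stable fixed point of the subthreshold dynamics, obtained from
#' \eqn{0.04 v^2 + 5 v + 140 - b v = 0} (taking the lower root) together with
#' \eqn{u = b v}.
#'
#' @param params A parameter list as returned by [neuron_params()].
#' @return A list with components \code{v} and \code{u}.
#' @export
neuron_rest <- function(params = neuron_params("RS")) {
  b <- params$b
  disc <- sqrt((5 - b)^2 - 4 * 0.04 * 140)
  v <- (-(5 - b) - disc) / (2 * 0.04)
  list(v = v, u = b * v)
}

#' Advance a single neuron by one time step
#'
#' One step of the integration scheme used throughout the simulator: the
#' membrane potential \eqn{v} is advanced with two half-steps of the quadratic
#' dynamics (for numerical stability near the spike upstroke) and the recovery
#' variable \eqn{u} with a single full step. If \eqn{v} reaches +30 mV the
#' neuron spikes and the after-spike resetting is applied.
#'
#' @param state List with components \code{v} (mV) and \code{u}.
#' @param params Parameter list, see [neuron_params()].
#' @param input_current Summed synaptic drive for this step (mV equivalent).
#' @param dt Step size in ms; must be 1 (the global grid step). The two v
#'   half-steps are dt/2 each.
#' @return A list with components \code{state} (the new \code{v}, \code{u})
#'   and \code{spiked} (logical).
#' @examples
#' st <- neuron_rest()
#' neuron_step(st, neuron_params("RS"), input_current = 0)
#' @export
neuron_step <- function(state, params, input_current = 0, dt = 1) {
  if (!is.finite(state$v) || !is.finite(state$u))
    stop("neuron state is non-finite (v=", state$v, ", u=", state$u, ")")
  v <- state$v
  u <- state$u
  v <- v + (dt / 2) * (0.04 * v^2 + 5 * v + 140 - u + input_current)
  if (v < 30)
    v <- v + (dt / 2) * (0.04 * v^2 + 5 * v + 140 - u + input_current)
  u <- u + dt * params$a * (params$b * v - u)
  if (!is.finite(v) || !is.finite(u))
    stop("neuron state became non-finite during integration")
  if (v >= 30) {
    list(state = list(v = params$c, u = u + params$d), spiked = TRUE)
  } else {
    list(state = list(v = v, u = u), spiked = FALSE)
  }
}
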