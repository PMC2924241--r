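#' Plasticity configuration
#'
#' Collects the parameters of the two plasticity systems.
#'
#' \strong{Long-term STDP} acts on the base weights of excitatory-to-
#' excitatory synapses and is keyed to presynaptic spike \emph{arrival}
#' times: an arrival that precedes a postsynaptic spike by \eqn{\Delta t}
#' potentiates by \eqn{A_+ e^{-\Delta t/\tau_+}}, an arrival that follows it
#' depresses by \eqn{A_- e^{-\Delta t/\tau_-}}; weights are clipped to
#' \eqn{[0, w_{max}]} mV. Contributions are additive over all pairs unless
#' \code{nearest_neighbor} is set.
#'
#' \strong{Short-term mechanisms} (associative, seconds scale):
#' \itemize{
#'   \item \code{"stdp"}: the same STDP window applied to a per-synapse
#'     scaling addend \eqn{sd \in [sd_{min}, 1]} that multiplies transmission
#'     as \eqn{w (1 + sd)} and relaxes to 0 with time constant
#'     \code{tau_sd} (5 s). The +1 ceiling gives at most a 100\% temporary
#'     increase over baseline; the default increment 0.1 means roughly ten
#'     optimally timed pre-then-post pairs saturate it.
#'   \item \code{"nmda"}: each synapse carries an NMDA activation \eqn{g}
#'     that is incremented by every arrival and decays with
#'     \code{tau_nmda} (250 ms). When \eqn{g > \theta_{up}} coincident with a
#'     postsynaptic spike the synapse flips into an up-state in which
#'     transmission is \code{nmda_gain}-fold (10) stronger; the up-state
#'     persists until \eqn{g} falls below \eqn{\theta_{down}} (hysteresis).
#' }
#'
#' \code{rate_gain} multiplies all plasticity increments and models an
#' elevated neuromodulator level (e.g. dopamine); time-varying gain is passed
#' to [simulate()] as a schedule instead.
#'
#' @param longterm_on Enable long-term STDP (off by default: working-memory
#'   experiments on selected groups block it; learning experiments enable it).
#' @param A_plus,A_minus,tau_plus,tau_minus Long-term STDP magnitudes and
#'   window time constants (ms).
#' @param rate_gain Static multiplier on all plasticity increments.
#' @param nearest_neighbor Use nearest-neighbor instead of all-pairs pairing
#'   for the long-term rule.
#' @param shortterm_mode One of \code{"stdp"}, \code{"nmda"}, \code{"off"}.
#' @param st_A_plus,st_A_minus,st_tau_plus,st_tau_minus Short-term STDP
#'   increments and window constants (ms).
#' @param tau_sd Decay time constant of \code{sd} (ms).
#' @param sd_min Depression floor of \code{sd} (keeps transmission positive).
#' @param tau_nmda NMDA activation decay constant (ms).
#' @param theta_up,theta_down Hysteresis thresholds on \eqn{g}; defaults are
#'   set so that three arrivals within one \code{tau_nmda} exceed
#'   \code{theta_up}, with \code{theta_down = theta_up / 4}.
#' @param nmda_gain Up-state efficacy multiplier.
#' @param nmda_cap Somatic saturation of up-state transmission (mV): the
#'   dendritic NMDA spike is \code{nmda_gain}-fold at the compartment, but
#'   its somatic impact saturates; the default (16 mV, twice the default
#'   weight ceiling) gives the two short-term modes the same transmission
#'   range, which the mode-parity experiments rely on.
#' @return An object of class \code{polywm_plasticity}.
#' @export
plasticity_config <- function(longterm_on = FALSE,
                              A_plus = 0.1, A_minus = 0.12,
                              tau_plus = 20, tau_minus = 20,
                              rate_gain = 1, nearest_neighbor = FALSE,
                              shortterm_mode = c("stdp", "nmda", "off"),
                              st_A_plus = 0.1, st_A_minus = 0.12,
                              st_tau_plus = 20, st_tau_minus = 20,
                              tau_sd = 5000, sd_min = -0.5,
                              tau_nmda = 250, theta_up = 2.5,
                              theta_down = theta_up / 4, nmda_gain = 10,
                              nmda_cap = 16) {
  shortterm_mode <- match.arg(shortterm_mode)
  stopifnot(A_plus > 0, A_minus > 0, tau_plus > 0, tau_minus > 0,
            rate_gain >= 0, st_A_plus > 0, st_A_minus > 0, tau_sd > 0,
            sd_min <= 0, sd_min > -1, tau_nmda > 0,
            theta_down < theta_up, nmda_gain >= 1, nmda_cap > 0)
  structure(as.list(environment()), class = "polywm_plasticity")
}

#' Simulate the network
#'
#' Runs the millisecond main loop: (1) deliver all presynaptic spikes whose
#' emission time plus synaptic delay equals the current step, scaled by the
#' short-term state; (2) add background minis and stimulus currents;
#' (3) advance all neuron dynamics; (4) apply plasticity updates keyed to
#' arrival and spike times. Fully reproducible given \code{seed}.
#'
#' @param network A \code{polywm_network}. Its config supplies the mini rate
#'   and amplitude unless overridden.
#' @param duration_ms Simulated time (ms, positive integer).
#' @param stimulus Optional data frame of current injections with columns
#'   \code{time} (integer ms), \code{neuron} (1-based id), \code{amplitude}
#'   (mV). Unknown neuron ids raise an error before the run starts.
#' @param forced Optional data frame (\code{time}, \code{neuron}) of spikes
#'   forced to occur exactly at the given times (bypassing the dynamics);
#'   used for noise-free cascade simulation.
#' @param plasticity A [plasticity_config()].
#' @param gain_schedule Optional data frame (\code{time}, \code{lt_gain},
#'   \code{st_gain}) giving a step-function schedule of plasticity-rate
#'   multipliers (e.g. a neuromodulator pulse, or 0 to suppress short-term
#'   increments when erasing a memory). Multiplied by \code{rate_gain}.
#' @param mini_rate,mini_amplitude Optional overrides of the network config.
#' @param sd_subset Optional integer vector of synapse table rows whose mean
#'   short-term scaling is recorded separately from the remaining plastic
#'   synapses.
#' @param trace_dt Sampling interval of the short-term trace in ms
#'   (0 disables recording).
#' @param state Optional list \code{(v, u)} of initial neuron states;
#'   defaults to the resting state.
#' @param seed Integer seed for all randomness in the run.
#' @return A list of class \code{polywm_sim} with elements \code{raster}
#'   (data frame \code{time}, \code{neuron}, time-ordered), \code{network}
#'   (with updated weights and short-term state), \code{state} (final
#'   \code{v}, \code{u}), \code{sd_trace} (data frame \code{time},
#'   \code{subset}, \code{other}, or NULL), \code{duration},
#'   and \code{nmda} (per-synapse \code{g} and \code{up} when in NMDA mode).
#' @export
simulate <- function(network, duration_ms,
                     stimulus = NULL, forced = NULL,
                     plasticity = plasticity_config(),
                     gain_schedule = NULL,
                     mini_rate = NULL, mini_amplitude = NULL,
                     sd_subset = integer(0), trace_dt = 0,
                     state = NULL, seed = 1) {
  stopifnot(inherits(network, "polywm_network"),
            inherits(plasticity, "polywm_plasticity"))
  duration_ms <- as.integer(duration_ms)
  if (duration_ms <= 0) stop("duration_ms must be positive")
  n <- network$n
  syn <- network$syn
  cfg <- network$config
  if (is.null(mini_rate)) mini_rate <- cfg$mini_rate
  if (is.null(mini_amplitude)) mini_amplitude <- cfg$mini_amplitude

  as_events <- function(x, what, with_amp) {
    if (is.null(x) || nrow(x) == 0) {
      return(list(time = integer(0), neuron = integer(0), amp = numeric(0)))
    }
    if (any(x$neuron < 1 | x$neuron > n))
      stop("unknown ", what, " target neuron id(s): ",
           paste(unique(x$neuron[x$neuron < 1 | x$neuron > n]), collapse = ", "))
    o <- order(x$time)
    list(time = as.integer(round(x$time[o])),
         neuron = as.integer(x$neuron[o]) - 1L,
         amp = if (with_amp) as.numeric(x$amplitude[o]) else numeric(0))
  }
  stim <- as_events(stimulus, "stimulus", TRUE)
  frc <- as_events(forced, "forced-spike", FALSE)

  if (is.null(gain_schedule)) {
    gt <- numeric(0); gl <- numeric(0); gs <- numeric(0)
  } else {
    o <- order(gain_schedule$time)
    gt <- as.numeric(gain_schedule$time[o])
    gl <- as.numeric(gain_schedule$lt_gain[o]) * plasticity$rate_gain
    gs <- as.numeric(gain_schedule$st_gain[o]) * plasticity$rate_gain
  }
  if (length(gt) == 0 || gt[1] > 0) {
    gt <- c(0, gt)
    gl <- c(plasticity$rate_gain, gl)
    gs <- c(plasticity$rate_gain, gs)
  }

  if (is.null(state)) {
    rest_rs <- neuron_rest(neuron_params("RS"))
    rest_fs <- neuron_rest(neuron_params("FS"))
    v0 <- ifelse(network$exc, rest_rs$v, rest_fs$v)
    u0 <- ifelse(network$exc, rest_rs$u, rest_fs$u)
  } else {
    v0 <- state$v; u0 <- state$u
  }

  st_mode <- match(plasticity$shortterm_mode, c("off", "stdp", "nmda")) - 1L
  if (length(sd_subset))
    stopifnot(all(sd_subset >= 1), all(sd_subset <= length(syn$pre)))

  set.seed(as.integer(seed))
  res <- sim_core_cpp(
    n, network$params$a, network$params$b, network$params$c,
    network$params$d, v0, u0,
    as.integer(syn$pre) - 1L, as.integer(syn$post) - 1L,
    as.integer(syn$delay), syn$weight, syn$sd, syn$plastic,
    duration_ms, mini_rate, mini_amplitude,
    stim$time, stim$neuron, stim$amp,
    frc$time, frc$neuron,
    plasticity$longterm_on, plasticity$A_plus, plasticity$A_minus,
    plasticity$tau_plus, plasticity$tau_minus,
    plasticity$nearest_neighbor, cfg$w_max,
    st_mode, plasticity$st_A_plus, plasticity$st_A_minus,
    plasticity$st_tau_plus, plasticity$st_tau_minus,
    plasticity$tau_sd, plasticity$sd_min,
    plasticity$tau_nmda, plasticity$theta_up, plasticity$theta_down,
    plasticity$nmda_gain, plasticity$nmda_cap,
    gt, gl, gs,
    as.integer(sd_subset) - 1L, as.integer(trace_dt))

  network$syn$weight <- res$w
  network$syn$sd <- res$sd

  raster <- data.frame(time = res$spike_time,
                       neuron = res$spike_neuron + 1L)
  sd_trace <- NULL
  if (trace_dt > 0)
    sd_trace <- data.frame(time = res$trace_time,
                           subset = res$trace_subset,
                           other = res$trace_other)
  out <- list(raster = raster, network = network,
              state = list(v = res$v, u = res$u),
              sd_trace = sd_trace, duration = duration_ms,
              nmda = if (st_mode == 2L) list(g = res$nmda_g, up = res$nmda_up),
              seed = as.integer(seed))
  class(out) <- "polywm_sim"
  out
}

#' @export
print.polywm_sim <- function(x, ...) {
  cat("polywm simulation:", x$duration, "ms,", nrow(x$raster), "spikes\n")
  invisible(x)
}
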