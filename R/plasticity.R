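#' Closed-form STDP window
#'
#' Weight change for a single pre-arrival/post-spike pair separated by
#' \code{dt = t_post - t_arrival} (ms): potentiation
#' \eqn{A_+ e^{-\Delta t/\tau_+}} for \code{dt >= 0} (simultaneity counts as
#' potentiation, the arrival-before-fire reading), depression
#' \eqn{-A_- e^{-|\Delta t|/\tau_-}} for \code{dt < 0}.
#'
#' @param dt Post-spike time minus presynaptic arrival time (ms).
#' @param A_plus,A_minus,tau_plus,tau_minus Window parameters.
#' @return The signed change (vectorized over \code{dt}).
#' @export
stdp_window <- function(dt, A_plus = 0.1, A_minus = 0.12,
                        tau_plus = 20, tau_minus = 20) {
  ifelse(dt >= 0, A_plus * exp(-dt / tau_plus),
         -A_minus * exp(dt / tau_minus))
}

#' Fresh plasticity states for a single synapse
#'
#' Initializers for the per-synapse state passed to [longterm_update()],
#' [shortterm_update()] and [nmda_update()].
#'
#' @param w Initial weight (mV) for the long-term state.
#' @return A state list for the corresponding update function.
#' @export
new_longterm_state <- function(w = 0) {
  list(w = w, pre_trace = 0, post_trace = 0, t_pre = -Inf, t_post = -Inf)
}

#' Long-term STDP update for one synapse event
#'
#' Processes a single event on one synapse in event-time order. Events are
#' \code{"pre"} (a presynaptic spike \emph{arriving} at the synapse; the
#' relevant time is emission time plus conduction delay) or \code{"post"}
#' (a postsynaptic somatic spike). All-pairs additive eligibility traces
#' implement the exponential window of [stdp_window()]; the weight is clipped
#' to \eqn{[0, w_{max}]}.
#'
#' @param state Synapse state, initially
#'   \code{list(w = w0, pre_trace = 0, post_trace = 0, t_pre = -Inf,
#'   t_post = -Inf)}.
#' @param event \code{"pre"} or \code{"post"}.
#' @param t Event time (ms); must be nondecreasing across calls.
#' @param config A [plasticity_config()] (fields \code{A_plus},
#'   \code{A_minus}, \code{tau_plus}, \code{tau_minus}, \code{rate_gain},
#'   \code{nearest_neighbor} are used).
#' @param w_max Upper weight bound (mV).
#' @return The updated state with a \code{delta} field giving this event's
#'   weight change.
#' @export
longterm_update <- function(state, event = c("pre", "post"), t,
                            config = plasticity_config(longterm_on = TRUE),
                            w_max = 8) {
  event <- match.arg(event)
  g <- config$rate_gain
  w0 <- state$w
  if (event == "pre") {
    post_tr <- state$post_trace * exp(-(t - state$t_post) / config$tau_minus)
    state$w <- min(w_max, max(0, state$w - g * config$A_minus * post_tr))
    dec <- exp(-(t - state$t_pre) / config$tau_plus)
    state$pre_trace <- (if (config$nearest_neighbor) 0 else
                          state$pre_trace * dec) + 1
    state$t_pre <- t
  } else {
    pre_tr <- state$pre_trace * exp(-(t - state$t_pre) / config$tau_plus)
    state$w <- min(w_max, max(0, state$w + g * config$A_plus * pre_tr))
    dec <- exp(-(t - state$t_post) / config$tau_minus)
    state$post_trace <- (if (config$nearest_neighbor) 0 else
                           state$post_trace * dec) + 1
    state$t_post <- t
  }
  state$delta <- state$w - w0
  state
}

#' @param sd Initial scaling addend for the short-term state.
#' @rdname new_longterm_state
#' @export
new_shortterm_state <- function(sd = 0) {
  list(sd = sd, pre_trace = 0, post_trace = 0,
       t_pre = -Inf, t_post = -Inf, t_sd = 0)
}

#' Associative short-term STDP update for one synapse event
#'
#' Same window shape as the long-term rule, but applied to the per-synapse
#' scaling addend \code{sd} which is clipped to \eqn{[sd_{min}, 1]} and
#' relaxes toward 0 with time constant \code{tau_sd} between events.
#' Pre- or post-synaptic activity alone changes nothing (associativity).
#'
#' @param state Synapse short-term state, initially
#'   \code{list(sd = 0, pre_trace = 0, post_trace = 0, t_pre = -Inf,
#'   t_post = -Inf, t_sd = 0)}.
#' @param event \code{"pre"} (arrival), \code{"post"} (spike) or
#'   \code{"none"} (pure decay to time \code{t}).
#' @param t Event time (ms), nondecreasing across calls.
#' @param config A [plasticity_config()].
#' @return Updated state; \code{state$sd} is the value at time \code{t}.
#' @export
shortterm_update <- function(state, event = c("pre", "post", "none"), t,
                             config = plasticity_config()) {
  event <- match.arg(event)
  g <- config$rate_gain
  state$sd <- state$sd * exp(-(t - state$t_sd) / config$tau_sd)
  state$t_sd <- t
  clip <- function(x) min(1, max(config$sd_min, x))
  if (event == "pre") {
    post_tr <- state$post_trace * exp(-(t - state$t_post) / config$st_tau_minus)
    state$sd <- clip(state$sd - g * config$st_A_minus * post_tr)
    state$pre_trace <-
      state$pre_trace * exp(-(t - state$t_pre) / config$st_tau_plus) + 1
    state$t_pre <- t
  } else if (event == "post") {
    pre_tr <- state$pre_trace * exp(-(t - state$t_pre) / config$st_tau_plus)
    state$sd <- clip(state$sd + g * config$st_A_plus * pre_tr)
    state$post_trace <-
      state$post_trace * exp(-(t - state$t_post) / config$st_tau_minus) + 1
    state$t_post <- t
  }
  state
}

#' @rdname new_longterm_state
#' @export
new_nmda_state <- function() {
  list(g = 0, upstate = FALSE, t = 0, up_expire = -Inf)
}

#' NMDA-spike synapse mode update
#'
#' Per-synapse hysteresis dynamics: the NMDA activation \code{g} is
#' incremented by each presynaptic arrival and decays exponentially with
#' \code{tau_nmda}; the up-state switches on only when \code{g > theta_up}
#' coincident with a postsynaptic spike, and switches off when \code{g}
#' falls below \code{theta_down}. While in the up-state, synaptic efficacy is
#' \code{nmda_gain}-fold.
#'
#' @param state NMDA state (see [new_nmda_state()] internals:
#'   \code{list(g = 0, upstate = FALSE, t = 0, up_expire = -Inf)}).
#' @param pre_arrival Logical: a presynaptic spike arrives at time \code{t}.
#' @param post_spike Logical: the postsynaptic neuron spikes at time \code{t}.
#' @param t Event time (ms), nondecreasing across calls.
#' @param config A [plasticity_config()].
#' @return Updated state; \code{state$multiplier} gives the current efficacy
#'   multiplier (\code{nmda_gain} in the up-state, 1 otherwise).
#' @export
nmda_update <- function(state, pre_arrival = FALSE, post_spike = FALSE, t,
                        config = plasticity_config(shortterm_mode = "nmda")) {
  state$g <- state$g * exp(-(t - state$t) / config$tau_nmda)
  state$t <- t
  if (state$upstate && state$g < config$theta_down) state$upstate <- FALSE
  if (pre_arrival) {
    state$g <- state$g + 1
    if (state$upstate)
      state$up_expire <- t + config$tau_nmda * log(state$g / config$theta_down)
  }
  if (post_spike && state$g > config$theta_up) {
    state$upstate <- TRUE
    state$up_expire <- t + config$tau_nmda * log(state$g / config$theta_down)
  }
  state$multiplier <- if (state$upstate) config$nmda_gain else 1
  state
}

#' Effective synaptic transmission strength
#'
#' The strength actually delivered by a presynaptic spike: in short-term-STDP
#' mode \eqn{w (1 + sd)}; in NMDA mode \eqn{w} multiplied by the up-state
#' gain when the synapse is in the up-state.
#'
#' @param w Base weight (mV), in \eqn{[0, w_{max}]}.
#' @param shortterm Either a short-term STDP state (a list with an \code{sd}
#'   field) or an NMDA state (a list with an \code{upstate} field), or NULL
#'   for baseline transmission.
#' @param config A [plasticity_config()] (for \code{nmda_gain}).
#' @return Effective weight in mV.
#' @examples
#' effective_weight(8, list(sd = 1))    # 16: the +100% short-term ceiling
#' effective_weight(4, list(upstate = TRUE))  # 40: 10-fold NMDA up-state
#' @export
effective_weight <- function(w, shortterm = NULL,
                             config = plasticity_config()) {
  if (is.null(shortterm)) return(w)
  if (!is.null(shortterm$sd)) return(w * (1 + shortterm$sd))
  if (!is.null(shortterm$upstate))
    return(w * if (isTRUE(shortterm$upstate)) config$nmda_gain else 1)
  stop("shortterm must be a short-term STDP state, an NMDA state, or NULL")
}

#' Default parameters of the dendritic compartment demo
#'
#' Generic passive-membrane values; the NMDA maximal conductance is chosen as
#' 9 times the AMPA conductance so that the NMDA:AMPA current ratio equals
#' 9:1 where the magnesium-block factor equals 1 (full depolarization).
#'
#' @return A named list of parameters.
#' @export
nmda_demo_params <- function() {
  list(C = 1,            # membrane capacitance (uF/cm^2 scale)
       g_leak = 0.1,     # leak conductance
       E_leak = -70,     # leak reversal (mV)
       E_syn = 0,        # AMPA/NMDA reversal (mV)
       g_ampa = 0.03,    # maximal AMPA conductance per unit activation
       g_nmda = 0.27,    # maximal NMDA conductance (ratio 9:1)
       tau_ampa = 5,     # AMPA decay (ms)
       tau_nmda = 250,   # NMDA decay (ms)
       mg_v0 = -60,      # magnesium block fully closed at or below this V
       mg_v1 = -10,      # fully open (B = 1) at or above this V
       post_amp = 40,    # somatic-spike depolarization pulse (mV/ms)
       post_dur = 2,     # pulse duration (ms)
       dt = 0.05)        # integration step (ms)
}

#' Magnesium-block voltage nonlinearity of the demo compartment
#'
#' Piecewise-linear gate: 0 at or below \code{mg_v0}, 1 at or above
#' \code{mg_v1}, linear in between.
#'
#' @param v Membrane potential (mV), vectorized.
#' @param params See [nmda_demo_params()].
#' @return Gate value in [0, 1].
#' @export
mg_block <- function(v, params = nmda_demo_params()) {
  pmin(1, pmax(0, (v - params$mg_v0) / (params$mg_v1 - params$mg_v0)))
}

#' NMDA to AMPA current ratio at full depolarization
#'
#' Evaluates the NMDA and AMPA current expressions of the compartment demo at
#' a membrane potential where the magnesium-block factor equals 1, with equal
#' unit channel activations, and returns their ratio (the driving force
#' cancels, so the ratio equals the conductance ratio).
#'
#' @param params See [nmda_demo_params()].
#' @return The current ratio (9 with default conductances).
#' @export
nmda_ampa_ratio <- function(params = nmda_demo_params()) {
  v <- params$mg_v1 - 1e-9 + 1  # any potential at/above full unblock
  stopifnot(mg_block(v, params) == 1)
  i_nmda <- params$g_nmda * mg_block(v, params) * (v - params$E_syn)
  i_ampa <- params$g_ampa * (v - params$E_syn)
  i_nmda / i_ampa
}

#' Passive dendritic compartment with voltage-dependent NMDA conductance
#'
#' Integrates a single passive compartment receiving AMPA and NMDA input from
#' one synapse. Presynaptic spikes increment both channel activations (AMPA
#' decays in ms, NMDA in 250 ms); postsynaptic somatic spikes invade the
#' dendrite as brief depolarizing current pulses. Presynaptic input alone
#' yields small EPSPs (magnesium block); paired pre-then-post trains unblock
#' the NMDA conductance and flip the compartment into a sustained
#' depolarized plateau (an NMDA spike), the up-state regime that the network
#' model abstracts as a hysteretic efficacy multiplier.
#'
#' @param pre_spike_times,post_spike_times Sorted spike times (ms).
#' @param duration_ms Total integration time (ms).
#' @param params See [nmda_demo_params()].
#' @return A data frame with columns \code{time} and \code{v}.
#' @export
nmda_compartment_demo <- function(pre_spike_times, post_spike_times = numeric(0),
                                  duration_ms = 1000,
                                  params = nmda_demo_params()) {
  stopifnot(!is.unsorted(pre_spike_times), !is.unsorted(post_spike_times))
  dt <- params$dt
  nt <- ceiling(duration_ms / dt)
  tt <- (seq_len(nt) - 1) * dt
  v <- numeric(nt)
  v[1] <- params$E_leak
  s_a <- 0; s_n <- 0
  pre_i <- 1; post_end <- -Inf; post_i <- 1
  for (k in seq_len(nt - 1)) {
    t <- tt[k]
    while (pre_i <= length(pre_spike_times) && pre_spike_times[pre_i] <= t) {
      s_a <- s_a + 1; s_n <- s_n + 1
      pre_i <- pre_i + 1
    }
    while (post_i <= length(post_spike_times) && post_spike_times[post_i] <= t) {
      post_end <- post_spike_times[post_i] + params$post_dur
      post_i <- post_i + 1
    }
    i_post <- if (t < post_end) params$post_amp else 0
    vi <- v[k]
    i_leak <- -params$g_leak * (vi - params$E_leak)
    i_ampa <- -params$g_ampa * s_a * (vi - params$E_syn)
    i_nmda <- -params$g_nmda * mg_block(vi, params) * s_n * (vi - params$E_syn)
    v[k + 1] <- vi + dt * (i_leak + i_ampa + i_nmda + i_post) / params$C
    s_a <- s_a * exp(-dt / params$tau_ampa)
    s_n <- s_n * exp(-dt / params$tau_nmda)
  }
  data.frame(time = tt, v = v)
}
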