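#' Network configuration
#'
#' Collects the structural and drive parameters of the delayed spiking
#' network. The defaults describe the standard 1000-neuron cortical-like
#' network: 80\% regular-spiking excitatory neurons, 20\% fast-spiking
#' inhibitory interneurons, independent connection probability 0.1, integer
#' axonal conduction delays uniform in 1--20 ms on excitatory synapses and
#' 1 ms on inhibitory synapses, and excitatory weights bounded by
#' \code{w_max} = 8 mV so that three simultaneously arriving maximal
#' presynaptic spikes are needed to reliably fire a postsynaptic neuron.
#'
#' Background drive ("minis") is modeled as an independent Poisson train of
#' brief current pulses per neuron. \code{mini_amplitude} defaults to a value
#' calibrated (see [calibrate_minis()]) so that with \code{mini_rate} = 0.3
#' events/s the baseline excitatory multiunit rate is about 0.3 Hz in the
#' default mature network.
#'
#' @param n_neurons Total number of neurons.
#' @param excitatory_fraction Fraction of excitatory (RS) neurons.
#' @param connection_prob Independent probability that any ordered pair of
#'   distinct neurons is connected.
#' @param exc_delay_range Integer ms range (inclusive) for excitatory delays.
#' @param inh_delay Integer ms delay of all inhibitory synapses.
#' @param w_max Upper bound for excitatory weights (mV).
#' @param w_inh Fixed inhibitory weight (mV, negative). The default is set
#'   so that fast feedback inhibition keeps cued-group reactivation episodic
#'   rather than runaway.
#' @param mini_rate Background mini rate, events per second per neuron.
#' @param mini_amplitude Amplitude of one mini pulse (mV equivalent).
#' @param init_weights Initial excitatory weight scheme: \code{"mature"}
#'   emulates an STDP-evolved network with a bimodal weight distribution — a
#'   fraction \code{p_strong} of excitatory-to-excitatory synapses at
#'   \code{w_max}, the rest at 0 (excitatory-to-inhibitory synapses stay at
#'   \code{w_max}); \code{"growth"} draws small random weights for
#'   plasticity-driven development. A homogeneous all-maximal network is not
#'   offered: it is epileptic (any triggered cascade recruits the whole
#'   network), whereas the bimodal preset keeps triggered cascades confined
#'   to their group and the background asynchronous.
#' @param p_strong Fraction of E-to-E synapses at \code{w_max} under the
#'   \code{"mature"} scheme.
#' @param growth_max Upper bound of the uniform initial weights under the
#'   \code{"growth"} scheme (mV).
#' @return An object of class \code{polywm_config} (a list).
#' @export
network_config <- function(n_neurons = 1000,
                           excitatory_fraction = 0.8,
                           connection_prob = 0.1,
                           exc_delay_range = c(1L, 20L),
                           inh_delay = 1L,
                           w_max = 8,
                           w_inh = -6,
                           mini_rate = 0.3,
                           mini_amplitude = 20,
                           init_weights = c("mature", "growth"),
                           p_strong = 0.3,
                           growth_max = 1) {
  init_weights <- match.arg(init_weights)
  if (n_neurons < 2) stop("n_neurons must be at least 2")
  if (excitatory_fraction <= 0 || excitatory_fraction > 1)
    stop("excitatory_fraction must be in (0, 1]")
  if (connection_prob <= 0 || connection_prob > 1)
    stop("connection_prob must be in (0, 1]")
  exc_delay_range <- as.integer(exc_delay_range)
  if (length(exc_delay_range) != 2 || any(exc_delay_range < 1) ||
      exc_delay_range[1] > exc_delay_range[2])
    stop("exc_delay_range must be a positive integer interval [lo, hi]")
  if (inh_delay < 1) stop("inh_delay must be a positive integer")
  if (w_max <= 0) stop("w_max must be positive")
  if (w_inh > 0) stop("w_inh must be negative or zero")
  if (p_strong < 0 || p_strong > 1) stop("p_strong must be in [0, 1]")
  structure(list(n_neurons = as.integer(n_neurons),
                 excitatory_fraction = excitatory_fraction,
                 connection_prob = connection_prob,
                 exc_delay_range = exc_delay_range,
                 inh_delay = as.integer(inh_delay),
                 w_max = w_max, w_inh = w_inh,
                 mini_rate = mini_rate, mini_amplitude = mini_amplitude,
                 init_weights = init_weights, p_strong = p_strong,
                 growth_max = growth_max),
            class = "polywm_config")
}

#' Build a random delayed spiking network
#'
#' Draws the network structure from the configuration: neuron types (the
#' first \code{round(n * excitatory_fraction)} neurons are RS excitatory, the
#' rest FS inhibitory), independent Bernoulli connectivity over all ordered
#' pairs of distinct neurons, uniform integer excitatory delays and fixed
#' inhibitory delays, and initial weights per the configured scheme.
#' Only excitatory-to-excitatory synapses are plastic; excitatory-to-
#' inhibitory and all inhibitory weights never change.
#'
#' @param config A [network_config()] object.
#' @param seed Integer seed; the build is fully deterministic given it.
#' @return An object of class \code{polywm_network}: neuron types and
#'   parameters plus a synapse table (\code{pre}, \code{post}, \code{delay},
#'   \code{weight}, \code{sd}, \code{plastic}) sorted by presynaptic id.
#'   Neuron ids are 1-based.
#' @examples
#' net <- build_network(network_config(n_neurons = 50), seed = 1)
#' summary(factor(net$exc))
#' @export
build_network <- function(config = network_config(), seed = 1) {
  stopifnot(inherits(config, "polywm_config"))
  set.seed(as.integer(seed))
  n <- config$n_neurons
  n_exc <- round(n * config$excitatory_fraction)
  exc <- c(rep(TRUE, n_exc), rep(FALSE, n - n_exc))

  rs <- neuron_params("RS"); fs <- neuron_params("FS")
  prm <- list(a = ifelse(exc, rs$a, fs$a), b = ifelse(exc, rs$b, fs$b),
              c = ifelse(exc, rs$c, fs$c), d = ifelse(exc, rs$d, fs$d))

  pre <- integer(0); post <- integer(0)
  pre_l <- vector("list", n); post_l <- vector("list", n)
  p <- config$connection_prob
  for (i in seq_len(n)) {
    tgt <- which(stats::runif(n) < p)
    tgt <- tgt[tgt != i]
    pre_l[[i]] <- rep.int(i, length(tgt))
    post_l[[i]] <- tgt
  }
  pre <- unlist(pre_l); post <- unlist(post_l)
  m <- length(pre)
  exc_syn <- exc[pre]
  delay <- integer(m)
  lo <- config$exc_delay_range[1]; hi <- config$exc_delay_range[2]
  delay[exc_syn] <- sample(lo:hi, sum(exc_syn), replace = TRUE)
  delay[!exc_syn] <- config$inh_delay

  plastic <- exc_syn & exc[post]
  weight <- numeric(m)
  if (config$init_weights == "mature") {
    weight[exc_syn] <- config$w_max          # E->I stays maximal
    ee <- which(plastic)
    weight[ee] <- ifelse(stats::runif(length(ee)) < config$p_strong,
                         config$w_max, 0)
  } else {
    weight[exc_syn] <- stats::runif(sum(exc_syn), 0, config$growth_max)
  }
  weight[!exc_syn] <- config$w_inh

  net <- list(n = n, exc = exc, params = prm,
              syn = list(pre = pre, post = post, delay = delay,
                         weight = weight, sd = numeric(m),
                         plastic = plastic),
              config = config, seed = as.integer(seed))
  class(net) <- "polywm_network"
  net
}

#' @export
print.polywm_network <- function(x, ...) {
  cat("polywm network:", x$n, "neurons (",
      sum(x$exc), "excitatory /", sum(!x$exc), "inhibitory ),",
      length(x$syn$pre), "synapses\n")
  invisible(x)
}

#' Expand spike emissions into a per-millisecond delivery schedule
#'
#' Each emitted spike produces exactly one delivery per efferent synapse of
#' the emitting neuron, at emission time plus that synapse's conduction
#' delay (exact integer arithmetic; no deliveries are lost or duplicated).
#'
#' @param emissions A data frame with columns \code{time} (ms) and
#'   \code{neuron} (1-based id), e.g. a [simulate()] raster slice.
#' @param network A \code{polywm_network}.
#' @return A data frame with columns \code{time} (delivery time, ms),
#'   \code{synapse} (row index into the synapse table), \code{pre} and
#'   \code{post}, sorted by delivery time.
#' @export
arrival_schedule <- function(emissions, network) {
  stopifnot(is.data.frame(emissions), inherits(network, "polywm_network"))
  if (nrow(emissions) == 0)
    return(data.frame(time = numeric(0), synapse = integer(0),
                      pre = integer(0), post = integer(0)))
  syn <- network$syn
  idx_by_pre <- split(seq_along(syn$pre), syn$pre)
  out <- vector("list", nrow(emissions))
  key <- as.character(emissions$neuron)
  for (k in seq_len(nrow(emissions))) {
    s <- idx_by_pre[[key[k]]]
    if (is.null(s)) next
    out[[k]] <- data.frame(time = emissions$time[k] + syn$delay[s],
                           synapse = s, pre = syn$pre[s], post = syn$post[s])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(time = numeric(0), synapse = integer(0),
                      pre = integer(0), post = integer(0)))
  res <- res[order(res$time, res$synapse), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Calibrate the mini amplitude against a target background rate
#'
#' Bisection on the mini amplitude so that the mean excitatory multiunit
#' rate of the network under minis alone matches \code{target_hz}. Used once
#' to fix the package default; exposed so users can recalibrate after
#' changing structural parameters.
#'
#' @param config A [network_config()]; its \code{mini_amplitude} is ignored.
#' @param target_hz Target mean excitatory rate (Hz).
#' @param duration_ms Simulated time per evaluation (ms).
#' @param range Amplitude search interval (mV).
#' @param iter Bisection iterations.
#' @param seed Integer seed.
#' @return The calibrated amplitude (mV), with the evaluation trace as the
#'   \code{"trace"} attribute.
#' @export
calibrate_minis <- function(config = network_config(), target_hz = 0.3,
                            duration_ms = 20000, range = c(5, 30),
                            iter = 8, seed = 1) {
  net <- build_network(config, seed = seed)
  n_exc <- sum(net$exc)
  eval_rate <- function(amp) {
    net$config$mini_amplitude <- amp
    r <- simulate(net, duration_ms,
                  plasticity = plasticity_config(shortterm_mode = "off"),
                  seed = seed + 17)
    sum(net$exc[r$raster$neuron]) / (n_exc * duration_ms / 1000)
  }
  lo <- range[1]; hi <- range[2]
  trace <- data.frame(amp = numeric(0), rate = numeric(0))
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    rate <- eval_rate(mid)
    trace <- rbind(trace, data.frame(amp = mid, rate = rate))
    if (rate > target_hz) hi <- mid else lo <- mid
  }
  out <- (lo + hi) / 2
  attr(out, "trace") <- trace
  out
}
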