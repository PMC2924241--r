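# Independent oracles used across the suite.

# Naive per-event reference simulator: plain R loops over neuron_step() and
# arrival_schedule(); no plasticity, no minis. Independent of the compiled
# main loop, which it is used to cross-check spike-for-spike.
reference_sim <- function(network, duration, stimulus = NULL, forced = NULL) {
  n <- network$n
  prm <- network$params
  state <- lapply(seq_len(n), function(j) {
    r <- neuron_rest(list(a = prm$a[j], b = prm$b[j], c = prm$c[j], d = prm$d[j]))
    list(v = r$v, u = r$u)
  })
  syn <- network$syn
  idx_by_pre <- split(seq_along(syn$pre), syn$pre)
  deliveries <- list()  # per-time list of weights by target
  add_delivery <- function(deliveries, t, j, w) {
    key <- as.character(t)
    deliveries[[key]] <- c(deliveries[[key]], stats::setNames(w, j))
    deliveries
  }
  spikes <- data.frame(time = numeric(0), neuron = integer(0))
  for (t in 0:(duration - 1)) {
    I <- numeric(n)
    dv <- deliveries[[as.character(t)]]
    if (!is.null(dv))
      for (k in seq_along(dv)) {
        j <- as.integer(names(dv)[k]); I[j] <- I[j] + dv[k]
      }
    if (!is.null(stimulus)) {
      sel <- stimulus$time == t
      for (k in which(sel)) I[stimulus$neuron[k]] <- I[stimulus$neuron[k]] +
          stimulus$amplitude[k]
    }
    forced_now <- if (!is.null(forced)) forced$neuron[forced$time == t] else integer(0)
    for (j in seq_len(n)) {
      p <- list(a = prm$a[j], b = prm$b[j], c = prm$c[j], d = prm$d[j])
      if (j %in% forced_now) {
        spiked <- TRUE
        state[[j]] <- list(v = p$c, u = state[[j]]$u + p$d)
      } else {
        st <- neuron_step(state[[j]], p, I[j])
        state[[j]] <- st$state
        spiked <- st$spiked
      }
      if (spiked) {
        spikes <- rbind(spikes, data.frame(time = t, neuron = j))
        s <- idx_by_pre[[as.character(j)]]
        for (si in s)
          deliveries <- add_delivery(deliveries, t + syn$delay[si],
                                     syn$post[si], syn$weight[si])
      }
    }
  }
  rownames(spikes) <- NULL
  spikes
}

# Fine-timestep Euler integration of the two-variable neuron model,
# independent of neuron_step()'s half-step scheme.
reference_neuron_rate <- function(params, I, duration_ms, dt = 0.01) {
  r <- neuron_rest(params)
  v <- r$v; u <- r$u
  nspk <- 0L
  for (k in seq_len(round(duration_ms / dt))) {
    v <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
    u <- u + dt * params$a * (params$b * v - u)
    if (v >= 30) {
      nspk <- nspk + 1L
      v <- params$c; u <- u + params$d
    }
  }
  nspk / (duration_ms / 1000)
}

# Event-driven closed-form evolution of one synapse under the short-term
# STDP rule (independent of shortterm_update's incremental bookkeeping):
# all-pairs traces evaluated directly from the event history.
reference_shortterm <- function(events, config = plasticity_config()) {
  # events: data.frame(time, type in c("pre","post")), time-ordered
  sd <- 0; t_sd <- 0
  clip <- function(x) min(1, max(config$sd_min, x))
  for (i in seq_len(nrow(events))) {
    t <- events$time[i]
    sd <- sd * exp(-(t - t_sd) / config$tau_sd); t_sd <- t
    prior <- events[seq_len(i - 1), , drop = FALSE]
    if (events$type[i] == "pre") {
      posts <- prior$time[prior$type == "post"]
      if (length(posts))
        sd <- clip(sd - config$st_A_minus *
                     sum(exp(-(t - posts) / config$st_tau_minus)))
    } else {
      pres <- prior$time[prior$type == "pre"]
      if (length(pres))
        sd <- clip(sd + config$st_A_plus *
                     sum(exp(-(t - pres) / config$st_tau_plus)))
    }
  }
  list(sd = sd, at = events$time[nrow(events)])
}

# Small deterministic network shared by several tests: a chain that one
# forced spike can traverse.
tiny_chain_network <- function(weights = c(30, 30), delays = c(7, 4)) {
  cfg <- network_config(n_neurons = 3, excitatory_fraction = 1,
                        connection_prob = 0.5, w_max = max(weights),
                        mini_rate = 0)
  rs <- neuron_params("RS")
  net <- list(n = 3L, exc = rep(TRUE, 3),
              params = list(a = rep(rs$a, 3), b = rep(rs$b, 3),
                            c = rep(rs$c, 3), d = rep(rs$d, 3)),
              syn = list(pre = c(1L, 2L), post = c(2L, 3L),
                         delay = as.integer(delays), weight = weights,
                         sd = c(0, 0), plastic = c(TRUE, TRUE)),
              config = cfg, seed = 0L)
  class(net) <- "polywm_network"
  net
}

# Memoised heavy fixtures: built once per test run.
.fixture_env <- new.env(parent = emptyenv())

wm_fixture <- function() {
  if (is.null(.fixture_env$wm)) {
    cfg <- network_config(p_strong = 0)
    net <- build_network(cfg, seed = 1)
    ins <- insert_pngs(net, n_groups = 100, size = 40, duration = 200,
                       convergence = 3, redundancy = 2, seed = 2)
    .fixture_env$wm <- ins
  }
  .fixture_env$wm
}

wm_trial_fixture <- function() {
  if (is.null(.fixture_env$trial)) {
    ins <- wm_fixture()
    .fixture_env$trial <- run_wm_trial(ins$network, ins$templates[[1]],
                                       cue_times = 0, duration_ms = 21000,
                                       seed = 201)
  }
  .fixture_env$trial
}

wm_batch_fixture <- function(n_trials = 20) {
  if (is.null(.fixture_env$batch)) {
    ins <- wm_fixture()
    net <- ins$network
    .fixture_env$batch <- lapply(seq_len(n_trials), function(k) {
      tpl <- ins$templates[[k]]
      tr <- run_wm_trial(net, tpl, cue_times = 0, duration_ms = 21000,
                         seed = 200 + k)
      mem <- unique(tpl$neuron)
      ev <- tr$activations[[1]]
      list(intra = mean_rate(tr$raster, mem, 1000, 21000),
           other = mean_rate(tr$raster, setdiff(which(net$exc), mem),
                             1000, 21000),
           last = if (nrow(ev)) max(ev$onset) - 1000 else 0,
           events = ev)
    })
  }
  .fixture_env$batch
}
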