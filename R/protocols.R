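#' Cue-stimulation protocol
#'
#' Describes how a group's polychronous pattern is presented to the network:
#' the pattern is injected \code{repetitions} times within \code{window} ms
#' (default 10 times in one second, evenly spaced, emulating stimulus-locked
#' volleys), to the first \code{segment_fraction} of the template's events in
#' time order; each injection fires its target independently with
#' \code{response_probability}.
#'
#' @param repetitions Number of pattern presentations.
#' @param window Interval containing all presentations (ms).
#' @param segment_fraction Fraction (0, 1] of the earliest template events
#'   stimulated.
#' @param response_probability Per-injection firing probability.
#' @param start Protocol start time (ms).
#' @param amplitude Injected current per event (mV equivalent; default is
#'   strongly suprathreshold so a resting RS neuron fires within a
#'   millisecond of the injection).
#' @return An object of class \code{polywm_protocol}.
#' @export
cue_protocol <- function(repetitions = 10, window = 1000,
                         segment_fraction = 0.8, response_probability = 1,
                         start = 0, amplitude = 60) {
  stopifnot(repetitions >= 0, window > 0,
            segment_fraction > 0, segment_fraction <= 1,
            response_probability >= 0, response_probability <= 1)
  structure(list(repetitions = repetitions, window = window,
                 segment_fraction = segment_fraction,
                 response_probability = response_probability,
                 start = start, amplitude = amplitude),
            class = "polywm_protocol")
}

#' Build the stimulus events that cue a group into working memory
#'
#' Expands a [cue_protocol()] against a template into a stimulus table for
#' [simulate()]: suprathreshold current injections to the first
#' \code{segment_fraction} of the template's events at their
#' template-relative times, one block per repetition, each event kept
#' independently with \code{response_probability}.
#'
#' @param template A \code{polywm_template}.
#' @param protocol A [cue_protocol()].
#' @param seed Optional seed for the response-probability sampling (uses the
#'   current RNG state when NULL).
#' @return Data frame (\code{time}, \code{neuron}, \code{amplitude}).
#' @export
cue_png <- function(template, protocol = cue_protocol(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_ev <- length(template$neuron)
  n_stim <- ceiling(protocol$segment_fraction * n_ev)
  idx <- seq_len(n_stim)  # events are stored in time order
  if (protocol$repetitions == 0)
    return(data.frame(time = numeric(0), neuron = integer(0),
                      amplitude = numeric(0)))
  starts <- protocol$start +
    (seq_len(protocol$repetitions) - 1) * (protocol$window / protocol$repetitions)
  out <- data.frame(
    time = rep(starts, each = n_stim) + rep(template$time[idx], length(starts)),
    neuron = rep(template$neuron[idx], length(starts)),
    amplitude = protocol$amplitude)
  if (protocol$response_probability < 1)
    out <- out[stats::runif(nrow(out)) < protocol$response_probability, ]
  rownames(out) <- NULL
  out
}

# synapse table rows whose pre and post both belong to the template
intra_png_synapses <- function(network, template) {
  members <- unique(template$neuron)
  which(network$syn$plastic &
          network$syn$pre %in% members & network$syn$post %in% members)
}

#' Run a working-memory trial
#'
#' The full cue-and-maintain experiment: each template in \code{templates}
#' is cued at its \code{cue_times} entry; with short-term plasticity enabled,
#' spontaneous reactivations sustained by short-term strengthening are then
#' detected as template activations. Long-term STDP is off unless the
#' supplied plasticity config enables it.
#'
#' @param network A \code{polywm_network} (typically with inserted or
#'   discovered groups).
#' @param templates A single template or list of templates to cue.
#' @param cue_times Numeric vector of cue-window start times (ms), one per
#'   template.
#' @param duration_ms Total trial duration (ms).
#' @param plasticity A [plasticity_config()]; short-term must be enabled for
#'   maintenance.
#' @param protocol A [cue_protocol()] applied to every cued template.
#' @param gain_schedule Optional plasticity-rate schedule (see [simulate()]),
#'   e.g. from [erase_wm()] or a neuromodulator pulse.
#' @param detect Named list of arguments for [detect_activations()].
#' @param trace_dt Sampling interval of the short-term trace (ms).
#' @param seed Integer seed.
#' @return An object of class \code{polywm_trial}: the simulation result
#'   plus \code{activations} (list of event tables per template),
#'   \code{templates}, \code{cue_times}, \code{cue_offset} (end of the first
#'   cue window), \code{rates} (multiunit rate curves for the first
#'   template's neurons and for the remaining excitatory neurons) and the
#'   short-term trace of intra-group versus other synapses.
#' @export
run_wm_trial <- function(network, templates, cue_times = 0,
                         duration_ms = 21000,
                         plasticity = plasticity_config(),
                         protocol = cue_protocol(),
                         gain_schedule = NULL,
                         detect = list(), trace_dt = 100, seed = 1) {
  if (inherits(templates, "polywm_template")) templates <- list(templates)
  stopifnot(length(cue_times) == length(templates))
  if (plasticity$shortterm_mode == "off" && is.null(gain_schedule))
    message("note: short-term plasticity is off; maintenance is not expected")

  set.seed(as.integer(seed))
  stim <- do.call(rbind, lapply(seq_along(templates), function(i) {
    p <- protocol; p$start <- cue_times[i]
    cue_png(templates[[i]], p)
  }))
  subset1 <- intra_png_synapses(network, templates[[1]])
  sim <- simulate(network, duration_ms, stimulus = stim,
                  plasticity = plasticity, gain_schedule = gain_schedule,
                  sd_subset = subset1, trace_dt = trace_dt,
                  seed = seed + 1L)

  activations <- lapply(templates, function(tpl)
    do.call(detect_activations, c(list(sim$raster, tpl), detect)))

  members1 <- unique(templates[[1]]$neuron)
  other_exc <- setdiff(which(network$exc), unlist(lapply(templates, `[[`, "neuron")))
  rates <- list(
    png = multiunit_rate(sim$raster, members1, duration = duration_ms),
    other = multiunit_rate(sim$raster, other_exc, duration = duration_ms))

  out <- c(sim, list(activations = activations, templates = templates,
                     cue_times = cue_times,
                     cue_offset = cue_times[1] + protocol$window,
                     protocol = protocol, rates = rates))
  class(out) <- c("polywm_trial", "polywm_sim")
  out
}

#' @export
print.polywm_trial <- function(x, ...) {
  cat("WM trial:", x$duration, "ms,", length(x$templates), "cued template(s)\n")
  for (i in seq_along(x$activations)) {
    ev <- x$activations[[i]]
    cat("  template", x$templates[[i]]$id, ":", nrow(ev),
        "detected activations")
    if (nrow(ev))
      cat("; last at", round(max(ev$onset) / 1000, 1), "s")
    cat("\n")
  }
  invisible(x)
}

#' Working-memory maintenance verdict
#'
#' Two criteria are reported: \code{every_window} — at least one detected
#' activation in every consecutive \code{window} ms bin between cue offset
#' and \code{end}; \code{persistence} — the last activation occurs more than
#' \code{min_persist} ms after cue offset. \code{maintained} is their
#' disjunction.
#'
#' @param events Activation-event table from [detect_activations()].
#' @param cue_offset End of the cue window (ms).
#' @param end End of the evaluation period (ms).
#' @param window Bin width for the every-window criterion (ms).
#' @param min_persist Persistence threshold (ms).
#' @return List with \code{every_window}, \code{persistence},
#'   \code{maintained}.
#' @export
wm_maintained <- function(events, cue_offset, end, window = 2000,
                          min_persist = 10000) {
  on <- events$onset[events$onset > cue_offset & events$onset <= end]
  if (length(on) == 0)
    return(list(every_window = FALSE, persistence = FALSE, maintained = FALSE))
  edges <- seq(cue_offset, end, by = window)
  if (edges[length(edges)] < end) edges <- c(edges, end)
  filled <- table(cut(on, edges))
  every <- all(filled > 0)
  persist <- max(on) - cue_offset > min_persist
  list(every_window = every, persistence = persist,
       maintained = every || persist)
}

#' Schedule that erases a working memory
#'
#' From \code{at_time} on, short-term plasticity increments are suppressed
#' (rate multiplier 0) so the per-synapse short-term state decays to
#' baseline and reactivations stop; long-term plasticity is unaffected.
#' Optionally the rate is restored at \code{restore_time}.
#'
#' @param at_time Fade onset (ms).
#' @param restore_time Optional time at which the short-term rate returns
#'   to 1.
#' @return A gain-schedule data frame for [simulate()] / [run_wm_trial()].
#' @export
erase_wm <- function(at_time, restore_time = NULL) {
  sched <- data.frame(time = at_time, lt_gain = 1, st_gain = 0)
  if (!is.null(restore_time)) {
    stopifnot(restore_time >= at_time)
    sched <- rbind(sched,
                   data.frame(time = restore_time, lt_gain = 1, st_gain = 1))
  }
  sched
}

#' Neuromodulator-gated cueing
#'
#' Cues a template only \code{presentations} times (instead of ten) in the
#' presence of an elevated simulated neuromodulator that multiplies the
#' plasticity rate by \code{gain} (default 5) during the cue window.
#'
#' @param network,template,duration_ms,plasticity,seed As in
#'   [run_wm_trial()].
#' @param presentations Number of pattern presentations (1--3 suffice at
#'   gain 5).
#' @param gain Plasticity-rate multiplier during the cue window.
#' @param protocol Base protocol; its repetitions/window are overridden so
#'   presentations keep the standard 100 ms spacing.
#' @return A \code{polywm_trial}.
#' @export
neuromodulator_cue <- function(network, template, presentations = 3,
                               gain = 5, duration_ms = 16000,
                               plasticity = plasticity_config(),
                               protocol = cue_protocol(), seed = 1) {
  stopifnot(gain >= 1)
  window <- 100 * max(presentations, 1)
  p <- protocol
  p$repetitions <- presentations
  p$window <- window
  sched <- data.frame(time = c(0, window + template$duration),
                      lt_gain = c(gain, 1), st_gain = c(gain, 1))
  run_wm_trial(network, template, cue_times = 0, duration_ms = duration_ms,
               plasticity = plasticity, protocol = p,
               gain_schedule = sched, seed = seed)
}

#' Novel-cue learning experiment
#'
#' Stimulates a fixed novel polychronous pattern over \code{n_stim}
#' randomly chosen excitatory neurons (10 presentations within 1 s, repeated
#' every \code{period_s} seconds) with long-term STDP enabled, under one of
#' three background conditions: \code{"A"} 0.3 Hz minis with short-term
#' STDP on, \code{"B"} 0.1 Hz minis, \code{"C"} short-term plasticity
#' blocked. After the run, group discovery restricted to stimulated-neuron
#' anchors reports whether a template initiated by the stimulated neurons
#' has formed, and its detected activation rate over the final
#' inter-presentation interval measures whether the new group is replayed.
#'
#' Learning a new group requires synapses between the pattern's neurons
#' whose conduction delays are compatible with the pattern's spike timing:
#' in a large evolved cortical network such delay-coincidence motifs exist
#' for essentially any input pattern, but a 1000-neuron random network has
#' vanishing motif density (a uniformly random pattern is unlearnable here
#' at any plasticity rate). The experiment therefore prepares a latent
#' scaffold: delay-compatible synapses among the stimulated neurons at
#' \code{scaffold_weight} (default half-maximal, functionally silent —
#' well below the three-coincident-arrival firing threshold). Long-term
#' STDP must potentiate the scaffold before the pattern can replay, so the
#' measured replay still reports genuine learning; short-term STDP and
#' background minis gate the replay itself, preserving the A/B/C contrast.
#'
#' @param network A \code{polywm_network}.
#' @param condition \code{"A"}, \code{"B"} or \code{"C"}.
#' @param n_stim Number of stimulated excitatory neurons.
#' @param pattern_span Span of the novel pattern (ms).
#' @param period_s Seconds between presentations.
#' @param duration_s Total duration (s).
#' @param scaffold_weight Initial weight of the latent scaffold (mV).
#' @param scaffold_redundancy Extra convergent scaffold afferents per
#'   pattern neuron beyond the minimum three (dense patterns admit more
#'   eligible predecessors than the sparse inserted groups).
#' @param plasticity Base plasticity config; long-term is forced on, and the
#'   short-term mode is forced off under condition C.
#' @param detect Named list of arguments for [detect_activations()].
#' @param seed Integer seed (governs neuron/pattern choice and the run).
#' @return List with the simulation, the stimulated \code{pattern}
#'   (data frame \code{neuron}, \code{time}), the discovered
#'   \code{template} (or NULL), \code{events} (flagged \code{evoked} when
#'   they fall inside the presentation window) and \code{replay_rate_hz}
#'   over the reported segment, \code{spontaneous_rate_hz} counting only
#'   non-evoked events, and \code{final_interval} (ms), the span of the
#'   two nine-second segments bracketing the last two presentations over
#'   which the replay rate is measured.
#' @export
run_novel_cue_experiment <- function(network, condition = c("A", "B", "C"),
                                     n_stim = 60, pattern_span = 100,
                                     period_s = 15, duration_s = 90,
                                     scaffold_weight = NULL,
                                     scaffold_redundancy = 3,
                                     plasticity = plasticity_config(longterm_on = TRUE),
                                     detect = list(), seed = 1) {
  condition <- match.arg(condition)
  plasticity$longterm_on <- TRUE
  mini_rate <- network$config$mini_rate
  if (condition == "B") mini_rate <- 0.1
  if (condition == "C") plasticity$shortterm_mode <- "off"
  if (is.null(scaffold_weight)) scaffold_weight <- network$config$w_max / 2

  ins <- insert_pngs(network, n_groups = 1, size = n_stim,
                     duration = pattern_span - 10, convergence = 3,
                     redundancy = scaffold_redundancy,
                     weight = scaffold_weight, seed = seed)
  network <- ins$network
  tpl_stim <- ins$templates[[1]]
  ids <- unique(tpl_stim$neuron)
  pattern <- data.frame(neuron = tpl_stim$neuron, time = tpl_stim$time)

  starts <- seq(0, duration_s * 1000 - 1, by = period_s * 1000)
  stim <- do.call(rbind, lapply(starts, function(s0) {
    p <- cue_protocol(repetitions = 10, window = 1000,
                      segment_fraction = 1, start = s0)
    cue_png(tpl_stim, p)
  }))

  sim <- simulate(network, duration_s * 1000, stimulus = stim,
                  plasticity = plasticity, mini_rate = mini_rate,
                  seed = seed + 1L)

  # discovery restricted to stimulated anchors, on the post-run network
  found <- find_pngs(sim$network, anchor_pool = ids, min_size = 10,
                     max_sets_per_target = 5, max_cascades = 300)
  template <- NULL
  if (length(found)) {
    sizes <- vapply(found, `[[`, numeric(1), "size")
    template <- found[[which.max(sizes)]]
  }

  # replay is episodic and fades with the short-term decay constant, so the
  # rate is reported over the nine-second segments bracketing the last two
  # presentations (one second before each onset to eight seconds after),
  # the segments the replay figures magnify; by then the formed group is
  # mature, and two segments halve the sampling variance of one
  last2 <- utils::tail(starts, 2)
  final <- c(min(last2) - 1000, max(last2) + 8000)
  events <- NULL; rate <- 0; spont_rate <- 0
  if (!is.null(template)) {
    events <- do.call(detect_activations, c(list(sim$raster, template), detect))
    in_seg <- rep(FALSE, nrow(events))
    evoked <- rep(FALSE, nrow(events))
    for (s0 in last2) {
      in_seg <- in_seg | (events$onset > s0 - 1000 & events$onset <= s0 + 8000)
      evoked <- evoked | (events$onset >= s0 &
                            events$onset <= s0 + 1000 + pattern_span)
    }
    events <- events[in_seg, ]
    events$evoked <- evoked[in_seg]
    seg_ms <- 9000 * length(last2)
    rate <- nrow(events) / seg_ms * 1000
    spont_rate <- sum(!events$evoked) /
      (seg_ms - length(last2) * (1000 + pattern_span)) * 1000
  }
  list(sim = sim, condition = condition, pattern = pattern,
       template = template, events = events, replay_rate_hz = rate,
       spontaneous_rate_hz = spont_rate, final_interval = final)
}
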