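#' Construct a polychronous group template
#'
#' A template is a group's stereotyped polychronous pattern: ordered
#' (neuron, relative time) events with relative times starting at 0, plus the
#' anchor subset whose correctly timed firing initiates the cascade.
#'
#' @param neuron Integer vector of 1-based neuron ids, one per event.
#' @param time Numeric vector of relative event times (ms).
#' @param anchors Integer vector of anchor neuron ids (a subset of
#'   \code{neuron}).
#' @param id Template identifier.
#' @return An object of class \code{polywm_template} with fields
#'   \code{id}, \code{neuron}, \code{time} (event-ordered), \code{anchors},
#'   \code{size} (number of distinct neurons) and \code{duration} (ms).
#' @export
png_template <- function(neuron, time, anchors = integer(0), id = 1L) {
  stopifnot(length(neuron) == length(time), length(neuron) > 0)
  o <- order(time, neuron)
  neuron <- as.integer(neuron[o])
  time <- as.numeric(time[o]) - min(time)
  if (!all(anchors %in% neuron))
    stop("anchors must be a subset of the template's neurons")
  structure(list(id = id, neuron = neuron, time = time,
                 anchors = as.integer(anchors),
                 size = length(unique(neuron)),
                 duration = max(time) - min(time)),
            class = "polywm_template")
}

#' @export
print.polywm_template <- function(x, ...) {
  cat("PNG template", x$id, ":", x$size, "neurons,",
      round(x$duration), "ms,", length(x$anchors), "anchors\n")
  invisible(x)
}

#' Simulate the noise-free cascade triggered by anchor firings
#'
#' Forces the anchor neurons to fire at the given times in a deterministic,
#' noise-free, plasticity-frozen copy of the network, and records the full
#' cascade: downstream neurons fire when converging presynaptic arrivals
#' drive them past threshold. Returns the realized (neuron, time) pattern as
#' a template, or NULL if the cascade dies before reaching
#' \code{min_size} distinct neurons.
#'
#' @param network A \code{polywm_network}.
#' @param anchors Data frame with columns \code{neuron}, \code{time} (ms).
#' @param min_size Minimum number of distinct neurons for a viable group.
#' @param horizon Extra simulated time after the last anchor (ms).
#' @param id Id given to the returned template.
#' @return A \code{polywm_template} or NULL.
#' @export
simulate_template <- function(network, anchors, min_size = 4,
                              horizon = 500, id = 1L) {
  stopifnot(is.data.frame(anchors), nrow(anchors) >= 1)
  dur <- as.integer(max(anchors$time) + horizon)
  sim <- simulate(network, dur, forced = anchors,
                  plasticity = plasticity_config(shortterm_mode = "off"),
                  mini_rate = 0, seed = 0)
  r <- sim$raster
  if (length(unique(r$neuron)) < min_size) return(NULL)
  png_template(r$neuron, r$time, anchors = unique(anchors$neuron), id = id)
}

# fraction of events of template a matched in template b within +/- tol ms
# after aligning both to relative time 0
template_overlap_frac <- function(a, b, tol = 1) {
  na <- length(a$neuron); nb <- length(b$neuron)
  matched <- 0L
  for (k in seq_len(na)) {
    hit <- b$neuron == a$neuron[k] & abs(b$time - a$time[k]) <= tol
    if (any(hit)) matched <- matched + 1L
  }
  matched / max(na, nb)
}

#' Discover polychronous groups from network structure
#'
#' Enumerates candidate anchor sets: for each postsynaptic target, sets of
#' \code{anchor_count} distinct presynaptic neurons whose synapses onto the
#' target are strong (weight above \code{strong_frac} of \code{w_max}). Each
#' set is fired with timing offsets that make the arrivals at the shared
#' target coincide, the noise-free cascade is simulated, and cascades
#' reaching \code{min_size} neurons are kept. Near-identical templates
#' (at least \code{dedupe_frac} of events coinciding within ±1 ms) are
#' deduplicated, first-found kept.
#'
#' @param network A \code{polywm_network}.
#' @param anchor_count Number of anchor neurons (3 matches the number of
#'   simultaneous maximal arrivals needed to fire a neuron).
#' @param min_size Minimum cascade size kept.
#' @param strong_frac Strong-synapse threshold as a fraction of \code{w_max}.
#' @param anchor_pool Optional integer vector restricting anchors to a subset
#'   of neurons (e.g. the stimulated neurons of a learning experiment).
#' @param max_sets_per_target Enumeration cap per postsynaptic target.
#' @param max_cascades Total cascade-simulation budget.
#' @param dedupe_frac Event-overlap fraction above which two templates are
#'   considered duplicates.
#' @param horizon Cascade simulation horizon (ms).
#' @param progress Print progress every so many targets (0 = quiet).
#' @return A list of \code{polywm_template} objects.
#' @export
find_pngs <- function(network, anchor_count = 3, min_size = 5,
                      strong_frac = 0.95, anchor_pool = NULL,
                      max_sets_per_target = 20, max_cascades = 2000,
                      dedupe_frac = 0.9, horizon = 500, progress = 0) {
  syn <- network$syn
  w_max <- network$config$w_max
  strong <- which(syn$plastic & syn$weight >= strong_frac * w_max)
  if (!is.null(anchor_pool))
    strong <- strong[syn$pre[strong] %in% anchor_pool]
  if (length(strong) == 0) return(list())
  by_post <- split(strong, syn$post[strong])

  templates <- list()
  n_casc <- 0L
  targets <- names(by_post)
  for (ti in seq_along(targets)) {
    s_idx <- by_post[[ti]]
    if (length(unique(syn$pre[s_idx])) < anchor_count) next
    combos <- utils::combn(s_idx, anchor_count, simplify = FALSE)
    # anchors must be distinct neurons (a pair may be joined by several
    # synapses with different delays; each delay set is its own candidate)
    combos <- Filter(function(cmb) !anyDuplicated(syn$pre[cmb]), combos)
    if (length(combos) > max_sets_per_target)
      combos <- combos[seq_len(max_sets_per_target)]
    for (cmb in combos) {
      if (n_casc >= max_cascades) break
      n_casc <- n_casc + 1L
      d <- syn$delay[cmb]
      anchors <- data.frame(neuron = syn$pre[cmb], time = max(d) - d)
      tpl <- simulate_template(network, anchors, min_size = min_size,
                               horizon = horizon,
                               id = length(templates) + 1L)
      if (is.null(tpl)) next
      dup <- any(vapply(templates, function(x)
        template_overlap_frac(tpl, x) >= dedupe_frac, logical(1)))
      if (!dup) templates[[length(templates) + 1L]] <- tpl
    }
    if (progress > 0 && ti %% progress == 0)
      message("find_pngs: ", ti, "/", length(targets), " targets, ",
              length(templates), " templates")
    if (n_casc >= max_cascades) break
  }
  templates
}

# firing latency (ms) of an RS neuron at rest hit by a current pulse
firing_latency <- function(amplitude, max_ms = 20) {
  prm <- neuron_params("RS")
  st <- neuron_rest(prm)
  for (t in 0:max_ms) {
    step <- neuron_step(st, prm, if (t == 0) amplitude else 0)
    if (step$spiked) return(t)
    st <- step$state
  }
  NA_integer_
}

#' Insert engineered polychronous groups into a network
#'
#' Adds synapses (with conduction delays chosen so that arrivals converge)
#' forming \code{n_groups} new PNGs. Each group consists of \code{size}
#' excitatory neurons firing at evenly spaced relative times spanning
#' \code{duration}; every non-anchor member receives at least
#' \code{convergence} convergent synapses from earlier intra-group neurons
#' (the first \code{convergence} neurons are the anchors and receive none),
#' with delays equal to the member's time minus the presynaptic time minus
#' the cascade firing latency, so that all arrivals coincide exactly when the
#' member is due to fire. \code{redundancy} requests that many extra
#' convergent afferents per member for noise robustness; extra afferents are
#' added where the delay range admits eligible earlier members (the delay
#' ceiling bounds how many can converge).
#'
#' @param network A \code{polywm_network}.
#' @param n_groups,size,duration Group count, neurons per group, pattern
#'   span (ms).
#' @param convergence Minimum convergent intra-group afferents per non-anchor
#'   member.
#' @param redundancy Extra afferents requested per member.
#' @param weight Weight given to the inserted synapses (mV); defaults to
#'   \code{w_max}. Sub-maximal values create a latent scaffold that
#'   long-term STDP can potentiate (used by the novel-cue experiment).
#' @param seed Integer seed for member sampling.
#' @return A list with the augmented \code{network} and the list of nominal
#'   \code{templates}.
#' @export
insert_pngs <- function(network, n_groups = 100, size = 40, duration = 200,
                        convergence = 3, redundancy = 1, weight = NULL,
                        seed = 1) {
  cfg <- network$config
  if (is.null(weight)) weight <- cfg$w_max
  exc_ids <- which(network$exc)
  if (length(exc_ids) < size) stop("not enough excitatory neurons")
  lag <- firing_latency(convergence * cfg$w_max)
  if (is.na(lag)) stop("convergent drive is subthreshold; increase w_max")
  d_lo <- cfg$exc_delay_range[1]; d_hi <- cfg$exc_delay_range[2]
  times <- round((seq_len(size) - 1) * duration / (size - 1))
  # feasibility: every non-anchor needs >= convergence earlier members whose
  # required delay falls inside the configured range; early members that are
  # too close to the pattern onset for that (dense patterns) become extra
  # anchors, but only within the leading fifth of the group
  n_afferent <- vapply((convergence + 1):size, function(k) {
    dk <- times[k] - lag - times[seq_len(k - 1)]
    sum(dk >= d_lo & dk <= d_hi)
  }, integer(1))
  infeasible <- (convergence + 1):size
  infeasible <- infeasible[n_afferent < convergence]
  anchor_cutoff <- max(convergence, ceiling(0.2 * size))
  if (any(infeasible > anchor_cutoff))
    stop("size/duration infeasible for the delay range: member ",
         min(infeasible[infeasible > anchor_cutoff]),
         " cannot receive ", convergence, " delay-compatible afferents")
  is_anchor <- seq_len(size) <= convergence | seq_len(size) %in% infeasible

  # per-member firing latency depends on how many afferents converge: the
  # delays must anticipate it so the realized cascade lands on the nominal
  # times (two passes resolve the mild latency/eligibility circularity)
  lat_of <- vapply(convergence:(convergence + redundancy + 2), function(nn)
    firing_latency(nn * weight), integer(1))
  member_take <- vector("list", size)
  member_delay <- vector("list", size)
  for (k in which(!is_anchor)) {
    dk <- times[k] - lag - times[seq_len(k - 1)]
    n_aff <- min(sum(dk >= d_lo & dk <= d_hi), convergence + redundancy)
    lag_k <- lat_of[n_aff - convergence + 1]
    if (is.na(lag_k)) lag_k <- lag
    dk <- times[k] - lag_k - times[seq_len(k - 1)]
    elig <- which(dk >= d_lo & dk <= d_hi)
    elig <- elig[order(dk[elig])]  # nearest (most recent) first
    take <- elig[seq_len(min(length(elig), convergence + redundancy))]
    member_take[[k]] <- take
    member_delay[[k]] <- as.integer(dk[take])
  }
  set.seed(as.integer(seed))
  new_pre <- integer(0); new_post <- integer(0); new_delay <- integer(0)
  templates <- vector("list", n_groups)
  for (gi in seq_len(n_groups)) {
    members <- sample(exc_ids, size)
    for (k in which(!is_anchor)) {
      take <- member_take[[k]]
      new_pre <- c(new_pre, members[take])
      new_post <- c(new_post, rep.int(members[k], length(take)))
      new_delay <- c(new_delay, member_delay[[k]])
    }
    templates[[gi]] <- png_template(members, times,
                                    anchors = members[is_anchor],
                                    id = gi)
  }
  m_new <- length(new_pre)
  syn <- network$syn
  syn$pre <- c(syn$pre, new_pre)
  syn$post <- c(syn$post, new_post)
  syn$delay <- c(syn$delay, new_delay)
  syn$weight <- c(syn$weight, rep.int(weight, m_new))
  syn$sd <- c(syn$sd, numeric(m_new))
  syn$plastic <- c(syn$plastic, rep.int(TRUE, m_new))
  o <- order(syn$pre)
  network$syn <- lapply(syn, function(x) x[o])
  list(network = network, templates = templates, lag = lag)
}

#' Detect template reactivations in a spike raster
#'
#' Scans candidate onsets: every raster spike of one of the template's early
#' neurons (the first \code{anchor_frac} of its events) anchors a candidate
#' alignment. For each candidate, the fraction of template events with a
#' spike of the right neuron within ±\code{jitter} ms of its expected time is
#' computed; alignments whose fraction strictly exceeds \code{min_fraction}
#' are reported after merging overlapping candidates to the best-matching
#' onset (greedy non-maximum suppression within \code{merge_window} ms).
#'
#' @param raster Data frame (\code{time}, \code{neuron}), time-sorted.
#' @param template A \code{polywm_template}.
#' @param min_fraction Detection threshold on the matched fraction (strict
#'   inequality).
#' @param jitter Allowed timing jitter (ms).
#' @param anchor_frac Fraction of earliest template events used to seed
#'   candidate alignments.
#' @param merge_window Suppression radius around an accepted onset (ms);
#'   defaults to half the template duration.
#' @return A data frame with one row per activation event: \code{id},
#'   \code{onset} (ms), \code{fraction}, \code{n_matched}.
#' @export
detect_activations <- function(raster, template, min_fraction = 0.25,
                               jitter = 5, anchor_frac = 0.2,
                               merge_window = NULL) {
  stopifnot(inherits(template, "polywm_template"))
  if (is.null(merge_window)) merge_window <- max(2 * jitter, template$duration / 2)
  ev_n <- template$neuron; ev_t <- template$time
  n_ev <- length(ev_n)
  empty <- data.frame(id = integer(0), onset = numeric(0),
                      fraction = numeric(0), n_matched = integer(0))
  if (nrow(raster) == 0) return(empty)

  spk <- split(raster$time, raster$neuron)
  spk <- lapply(spk, sort)

  n_seed <- max(1L, ceiling(anchor_frac * n_ev))
  onsets <- numeric(0)
  for (k in seq_len(n_seed)) {
    st <- spk[[as.character(ev_n[k])]]
    if (!is.null(st)) onsets <- c(onsets, st - ev_t[k])
  }
  onsets <- sort(unique(onsets))
  if (length(onsets) == 0) return(empty)

  counts <- integer(length(onsets))
  for (k in seq_len(n_ev)) {
    st <- spk[[as.character(ev_n[k])]]
    if (is.null(st)) next
    expect <- onsets + ev_t[k]
    # a spike within [expect - jitter, expect + jitter]?
    hi <- findInterval(expect + jitter, st)
    lo <- findInterval(expect - jitter - 1e-9, st)
    counts <- counts + as.integer(hi > lo)
  }
  frac <- counts / n_ev
  keep <- frac > min_fraction
  if (!any(keep)) return(empty)
  cand <- data.frame(onset = onsets[keep], fraction = frac[keep],
                     n_matched = counts[keep])
  cand <- cand[order(-cand$fraction, cand$onset), ]
  taken <- logical(nrow(cand))
  out <- list()
  for (i in seq_len(nrow(cand))) {
    if (taken[i]) next
    taken <- taken | abs(cand$onset - cand$onset[i]) <= merge_window
    out[[length(out) + 1L]] <- cand[i, ]
  }
  res <- do.call(rbind, out)
  res <- res[order(res$onset), ]
  data.frame(id = rep(template$id, nrow(res)), onset = res$onset,
             fraction = res$fraction, n_matched = res$n_matched,
             row.names = NULL)
}

#' Time-reversed surrogate raster
#'
#' Returns the raster with every spike time mapped to
#' \code{duration - time}, preserving neuron identities. Used as the null
#' for activation-frequency significance: a template's polychronous order is
#' destroyed while all single-neuron statistics are preserved. The mapping is
#' an involution for fixed \code{duration}.
#'
#' @param raster Data frame (\code{time}, \code{neuron}).
#' @param duration Total duration (ms); defaults to \code{max(raster$time)}.
#' @return The reversed raster, time-sorted.
#' @export
surrogate_raster <- function(raster, duration = NULL) {
  if (is.null(duration)) duration <- if (nrow(raster)) max(raster$time) else 0
  out <- data.frame(time = duration - raster$time, neuron = raster$neuron)
  out <- out[order(out$time, out$neuron), ]
  rownames(out) <- NULL
  out
}

#' Summary statistics of a set of polychronous groups
#'
#' Computes the group count, size and duration distributions, the pairwise
#' shared-neuron distribution, per-neuron membership counts, and — when a
#' raster is supplied — the activation-frequency distributions on the real
#' and on the time-reversed surrogate raster.
#'
#' @param templates Nonempty list of \code{polywm_template}s.
#' @param raster Optional raster for activation-frequency statistics.
#' @param n_neurons Number of neurons for the membership table (defaults to
#'   the largest id seen).
#' @param ... Passed to [detect_activations()].
#' @return An object of class \code{polywm_png_stats}: list with
#'   \code{count}, \code{sizes}, \code{durations}, \code{pair_overlap}
#'   (matrix of shared-neuron counts), \code{membership} (per-neuron counts),
#'   and optionally \code{activation_rate} and \code{surrogate_rate} (Hz per
#'   template).
#' @export
png_statistics <- function(templates, raster = NULL, n_neurons = NULL, ...) {
  stopifnot(length(templates) > 0)
  sizes <- vapply(templates, function(x) x$size, numeric(1))
  durations <- vapply(templates, function(x) x$duration, numeric(1))
  member_sets <- lapply(templates, function(x) unique(x$neuron))
  if (is.null(n_neurons)) n_neurons <- max(unlist(member_sets))
  membership <- tabulate(unlist(member_sets), nbins = n_neurons)
  k <- length(templates)
  pair <- matrix(0L, k, k)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ov <- length(intersect(member_sets[[i]], member_sets[[j]]))
      pair[i, j] <- ov; pair[j, i] <- ov
    }
  }
  out <- list(count = k, sizes = sizes, durations = durations,
              pair_overlap = pair, membership = membership)
  if (!is.null(raster) && nrow(raster) > 0) {
    dur_s <- max(raster$time) / 1000
    surr <- surrogate_raster(raster)
    out$activation_rate <- vapply(templates, function(tpl)
      nrow(detect_activations(raster, tpl, ...)) / dur_s, numeric(1))
    out$surrogate_rate <- vapply(templates, function(tpl)
      nrow(detect_activations(surr, tpl, ...)) / dur_s, numeric(1))
  }
  class(out) <- "polywm_png_stats"
  out
}

#' @export
print.polywm_png_stats <- function(x, ...) {
  cat("PNG statistics:", x$count, "groups; mean size",
      round(mean(x$sizes), 1), "neurons; mean duration",
      round(mean(x$durations), 1), "ms\n")
  if (x$count > 1)
    cat("mean pairwise shared neurons:",
        round(mean(x$pair_overlap[upper.tri(x$pair_overlap)]), 2), "\n")
  invisible(x)
}
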