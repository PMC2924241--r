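#' Multiunit firing-rate curve
#'
#' Spikes of the subset per bin divided by (bin width times subset size),
#' in Hz: the population-averaged rate per neuron.
#'
#' @param raster Data frame (\code{time}, \code{neuron}).
#' @param subset Nonempty integer vector of neuron ids to average over.
#' @param bin_ms Bin width (ms).
#' @param duration Total duration (ms); defaults to the last spike time
#'   rounded up to a full bin.
#' @return A data frame of class \code{polywm_rate}: \code{t0}, \code{t1}
#'   (bin edges, ms) and \code{rate} (Hz).
#' @export
multiunit_rate <- function(raster, subset, bin_ms = 100, duration = NULL) {
  if (length(subset) == 0) stop("subset must be nonempty")
  if (is.null(duration))
    duration <- if (nrow(raster)) ceiling(max(raster$time) / bin_ms) * bin_ms
                else bin_ms
  edges <- seq(0, duration, by = bin_ms)
  if (edges[length(edges)] < duration) edges <- c(edges, duration)
  tt <- raster$time[raster$neuron %in% subset]
  counts <- graphics::hist(tt, breaks = edges, plot = FALSE, right = FALSE)$counts
  widths <- diff(edges)
  out <- data.frame(t0 = edges[-length(edges)], t1 = edges[-1],
                    rate = counts / (widths / 1000) / length(subset))
  class(out) <- c("polywm_rate", "data.frame")
  out
}

#' Mean rate over a time window
#'
#' Convenience scalar: spikes of \code{subset} in \code{[from, to)} divided
#' by window length and subset size, in Hz.
#'
#' @param raster Data frame (\code{time}, \code{neuron}).
#' @param subset Neuron ids.
#' @param from,to Window (ms).
#' @return Rate in Hz.
#' @export
mean_rate <- function(raster, subset, from, to) {
  if (length(subset) == 0) stop("subset must be nonempty")
  n <- sum(raster$neuron %in% subset & raster$time >= from & raster$time < to)
  n / ((to - from) / 1000) / length(subset)
}

#' Coefficient of variation of interspike intervals
#'
#' Standard deviation of the ISIs divided by the mean ISI. A global measure:
#' inflated by slow nonstationarity of the firing rate.
#'
#' @param spike_times Sorted spike times of one neuron (ms); at least 3
#'   spikes are required (NA with a warning otherwise).
#' @return CV (>= 0), or NA.
#' @export
isi_cv <- function(spike_times) {
  if (length(spike_times) < 3) {
    warning("CV undefined for fewer than 3 spikes")
    return(NA_real_)
  }
  isi <- diff(sort(spike_times))
  stats::sd(isi) / mean(isi)
}

#' Local coefficient of variation (CV2)
#'
#' Mean over consecutive ISI pairs of \eqn{2 |I_{k+1} - I_k| / (I_{k+1} + I_k)}.
#' Robust to slow rate changes, unlike the global CV.
#'
#' @inheritParams isi_cv
#' @return CV2 in [0, 2], or NA.
#' @export
isi_cv2 <- function(spike_times) {
  if (length(spike_times) < 3) {
    warning("CV2 undefined for fewer than 3 spikes")
    return(NA_real_)
  }
  isi <- diff(sort(spike_times))
  i1 <- isi[-length(isi)]; i2 <- isi[-1]
  mean(2 * abs(i2 - i1) / (i2 + i1))
}

#' Per-neuron CV and CV2 over a raster window
#'
#' @param raster Data frame (\code{time}, \code{neuron}).
#' @param subset Neuron ids to analyze.
#' @param from,to Analysis window (ms).
#' @param min_spikes Minimum spikes per neuron.
#' @return Data frame (\code{neuron}, \code{n_spikes}, \code{cv},
#'   \code{cv2}); neurons with too few spikes are dropped.
#' @export
cv_stats <- function(raster, subset, from = 0, to = Inf, min_spikes = 3) {
  keep <- raster$neuron %in% subset & raster$time >= from & raster$time < to
  spl <- split(raster$time[keep], raster$neuron[keep])
  spl <- spl[lengths(spl) >= max(3, min_spikes)]
  if (length(spl) == 0)
    return(data.frame(neuron = integer(0), n_spikes = integer(0),
                      cv = numeric(0), cv2 = numeric(0)))
  data.frame(neuron = as.integer(names(spl)),
             n_spikes = lengths(spl),
             cv = vapply(spl, isi_cv, numeric(1)),
             cv2 = vapply(spl, isi_cv2, numeric(1)),
             row.names = NULL)
}

#' Cross-correlogram of two spike trains
#'
#' Counts of lag differences (b minus a) per bin within ±\code{max_lag},
#' normalized per reference (train a) spike.
#'
#' @param train_a,train_b Sorted spike times (ms); a is the reference.
#' @param max_lag Window half-width (ms).
#' @param bin Bin width (ms).
#' @return Data frame (\code{lag} bin centers, \code{count},
#'   \code{per_ref}).
#' @export
cross_correlogram <- function(train_a, train_b, max_lag = 50, bin = 1) {
  stopifnot(length(train_a) > 0, length(train_b) > 0)
  train_a <- sort(train_a); train_b <- sort(train_b)
  edges <- seq(-max_lag, max_lag, by = bin)
  counts <- numeric(length(edges) - 1)
  for (ta in train_a) {
    lo <- findInterval(ta - max_lag - 1e-9, train_b) + 1
    hi <- findInterval(ta + max_lag, train_b)
    if (hi >= lo) {
      lags <- train_b[lo:hi] - ta
      idx <- findInterval(lags, edges, rightmost.closed = TRUE)
      idx <- idx[idx >= 1 & idx <= length(counts)]
      tab <- tabulate(idx, nbins = length(counts))
      counts <- counts + tab
    }
  }
  data.frame(lag = (edges[-length(edges)] + edges[-1]) / 2,
             count = counts, per_ref = counts / length(train_a))
}

#' Working-memory duration
#'
#' Time of the last detected reactivation after the offset of stimulation.
#'
#' @param events Activation-event table ([detect_activations()]).
#' @param stim_offset Cue-window end (ms).
#' @return Last onset minus \code{stim_offset} (ms); 0 if there are no
#'   events after the offset (flagged with attribute \code{no_events}).
#' @export
wm_duration <- function(events, stim_offset) {
  on <- events$onset[events$onset > stim_offset]
  if (length(on) == 0) {
    out <- 0
    attr(out, "no_events") <- TRUE
    return(out)
  }
  max(on) - stim_offset
}

#' Working-memory capacity curve
#'
#' Mean number of simultaneously maintained items as a function of load.
#'
#' @param verdicts A list keyed by load: each element is a logical vector
#'   (or list of vectors over repeats) of per-item maintenance verdicts at
#'   that load.
#' @return Data frame (\code{load}, \code{held}) sorted by load.
#' @export
capacity_curve <- function(verdicts) {
  loads <- as.integer(names(verdicts))
  stopifnot(!any(is.na(loads)))
  held <- vapply(seq_along(verdicts), function(i) {
    v <- verdicts[[i]]
    if (is.list(v)) mean(vapply(v, sum, numeric(1))) else sum(v)
  }, numeric(1))
  out <- data.frame(load = loads, held = held)
  out[order(out$load), ]
}
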