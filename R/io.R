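#' Write a spike raster to tab-separated text
#'
#' Format: comment header lines starting with \code{#}, then two columns
#' \code{time_ms<TAB>neuron_id}. Neuron ids are written 0-based in the file
#' (the on-disk convention) and converted to the package's 1-based ids on
#' read.
#'
#' @param raster Data frame (\code{time}, \code{neuron}), 1-based ids.
#' @param path Output file.
#' @param n_neurons,duration Optional metadata recorded in the header.
#' @return \code{path}, invisibly.
#' @export
write_raster <- function(raster, path, n_neurons = NULL, duration = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# polywm spike raster v1", con)
  writeLines("# columns: time_ms\tneuron_id (0-based)", con)
  if (!is.null(n_neurons)) writeLines(paste0("# n_neurons: ", n_neurons), con)
  if (!is.null(duration)) writeLines(paste0("# duration_ms: ", duration), con)
  if (nrow(raster))
    writeLines(paste(format(raster$time, trim = TRUE, scientific = FALSE),
                     raster$neuron - 1L, sep = "\t"), con)
  invisible(path)
}

#' Read a spike raster from tab-separated text
#'
#' @param path Input file (format of [write_raster()]).
#' @return Data frame (\code{time}, \code{neuron}) with 1-based ids, sorted
#'   by time (a warning is raised if the file was unsorted).
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0)
    return(data.frame(time = numeric(0), neuron = integer(0)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    line_no <- which(!startsWith(lines, "#") & nzchar(lines))[bad[1]]
    stop("malformed raster line ", line_no, ": ", lines[line_no])
  }
  time <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  neuron <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  if (anyNA(time) || anyNA(neuron)) {
    line_no <- which(!startsWith(lines, "#") &
                       nzchar(lines))[which(is.na(time) | is.na(neuron))[1]]
    stop("malformed raster line ", line_no, ": ", lines[line_no])
  }
  out <- data.frame(time = time, neuron = neuron + 1L)
  if (is.unsorted(out$time)) {
    warning("raster file was not time-sorted; sorting on read")
    out <- out[order(out$time, out$neuron), ]
    rownames(out) <- NULL
  }
  out
}

#' Save a network to a plain-text container
#'
#' A metadata header (key/value lines: configuration, seed, format version)
#' followed by the flat synapse table (\code{pre}, \code{post}, \code{delay},
#' \code{weight}, \code{sd}, \code{plastic}). Numeric values are written with
#' full precision; the round trip is lossless.
#'
#' @param network A \code{polywm_network}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
save_network <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- network$config
  num <- function(x) formatC(x, digits = 17, format = "g")
  writeLines(c("# polywm network v1",
               paste0("# n: ", network$n),
               paste0("# seed: ", network$seed),
               paste0("# exc: ", paste(as.integer(network$exc), collapse = "")),
               paste0("# config.n_neurons: ", cfg$n_neurons),
               paste0("# config.excitatory_fraction: ", num(cfg$excitatory_fraction)),
               paste0("# config.connection_prob: ", num(cfg$connection_prob)),
               paste0("# config.exc_delay_range: ",
                      paste(cfg$exc_delay_range, collapse = " ")),
               paste0("# config.inh_delay: ", cfg$inh_delay),
               paste0("# config.w_max: ", num(cfg$w_max)),
               paste0("# config.w_inh: ", num(cfg$w_inh)),
               paste0("# config.mini_rate: ", num(cfg$mini_rate)),
               paste0("# config.mini_amplitude: ", num(cfg$mini_amplitude)),
               paste0("# config.init_weights: ", cfg$init_weights),
               paste0("# config.p_strong: ", num(cfg$p_strong)),
               paste0("# config.growth_max: ", num(cfg$growth_max)),
               "# columns: pre\tpost\tdelay\tweight\tsd\tplastic"), con)
  syn <- network$syn
  if (length(syn$pre))
    writeLines(paste(syn$pre, syn$post, syn$delay,
                     num(syn$weight), num(syn$sd),
                     as.integer(syn$plastic), sep = "\t"), con)
  invisible(path)
}

#' Load a network saved by [save_network()]
#'
#' @param path Input file.
#' @return A \code{polywm_network}.
#' @export
load_network <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "# polywm network v1")
    stop("not a polywm network file (or unsupported version): ", path)
  hdr <- lines[startsWith(lines, "# ")]
  get <- function(key) {
    pat <- paste0("# ", key, ": ")
    hit <- hdr[startsWith(hdr, pat)]
    if (length(hit) == 0) stop("network file is missing header field: ", key)
    substring(hit[1], nchar(pat) + 1)
  }
  n <- as.integer(get("n"))
  exc_str <- get("exc")
  if (nchar(exc_str) != n) stop("truncated or corrupt network file: ", path)
  cfg <- network_config(
    n_neurons = as.integer(get("config.n_neurons")),
    excitatory_fraction = as.numeric(get("config.excitatory_fraction")),
    connection_prob = as.numeric(get("config.connection_prob")),
    exc_delay_range = as.integer(strsplit(get("config.exc_delay_range"), " ")[[1]]),
    inh_delay = as.integer(get("config.inh_delay")),
    w_max = as.numeric(get("config.w_max")),
    w_inh = as.numeric(get("config.w_inh")),
    mini_rate = as.numeric(get("config.mini_rate")),
    mini_amplitude = as.numeric(get("config.mini_amplitude")),
    init_weights = get("config.init_weights"),
    p_strong = as.numeric(get("config.p_strong")),
    growth_max = as.numeric(get("config.growth_max")))
  exc <- strsplit(exc_str, "")[[1]] == "1"
  rs <- neuron_params("RS"); fs <- neuron_params("FS")
  prm <- list(a = ifelse(exc, rs$a, fs$a), b = ifelse(exc, rs$b, fs$b),
              c = ifelse(exc, rs$c, fs$c), d = ifelse(exc, rs$d, fs$d))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 6)) stop("truncated or corrupt network file: ", path)
    mat <- do.call(rbind, parts)
    syn <- list(pre = as.integer(mat[, 1]), post = as.integer(mat[, 2]),
                delay = as.integer(mat[, 3]), weight = as.numeric(mat[, 4]),
                sd = as.numeric(mat[, 5]), plastic = mat[, 6] == "1")
  } else {
    syn <- list(pre = integer(0), post = integer(0), delay = integer(0),
                weight = numeric(0), sd = numeric(0), plastic = logical(0))
  }
  net <- list(n = n, exc = exc, params = prm, syn = syn, config = cfg,
              seed = as.integer(get("seed")))
  class(net) <- "polywm_network"
  net
}

#' Write templates to a structured text file
#'
#' Per template: a header line \code{> id <id> anchors <a1,a2,...>} followed
#' by one \code{neuron,relative_time_ms} line per event.
#'
#' @param templates List of \code{polywm_template}s.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_templates <- function(templates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# polywm templates v1", con)
  for (tpl in templates) {
    writeLines(paste0("> id ", tpl$id, " anchors ",
                      paste(tpl$anchors, collapse = ",")), con)
    writeLines(paste(tpl$neuron,
                     formatC(tpl$time, digits = 17, format = "g"), sep = ","), con)
  }
  invisible(path)
}

#' Read templates written by [write_templates()]
#'
#' @param path Input file.
#' @return List of \code{polywm_template}s.
#' @export
read_templates <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  out <- list()
  cur <- NULL
  flush_cur <- function(cur) {
    if (is.null(cur) || length(cur$neuron) == 0) return(NULL)
    png_template(cur$neuron, cur$time, anchors = cur$anchors, id = cur$id)
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      tpl <- flush_cur(cur)
      if (!is.null(tpl)) out[[length(out) + 1L]] <- tpl
      m <- regmatches(ln, regexec("^> id (\\S+) anchors (\\S*)$", ln))[[1]]
      if (length(m) != 3) stop("malformed template header: ", ln)
      anchors <- if (nzchar(m[3]))
        as.integer(strsplit(m[3], ",")[[1]]) else integer(0)
      cur <- list(id = as.integer(m[2]), anchors = anchors,
                  neuron = integer(0), time = numeric(0))
    } else {
      p <- strsplit(ln, ",", fixed = TRUE)[[1]]
      if (length(p) != 2) stop("malformed template event line: ", ln)
      cur$neuron <- c(cur$neuron, as.integer(p[1]))
      cur$time <- c(cur$time, as.numeric(p[2]))
    }
  }
  tpl <- flush_cur(cur)
  if (!is.null(tpl)) out[[length(out) + 1L]] <- tpl
  out
}

#' Seven-neuron two-group toy network
#'
#' Builds a small network in which conduction delays arrange seven neurons
#' into two functional subnetworks ("red" and "black"): firing of neurons 1
#' and 2 with the appropriate relative timing triggers the same set of
#' neurons in two different polychronous orders. Synaptic weights are set so
#' that two coincident arrivals fire a neuron; each downstream neuron
#' receives one red and one black synapse from each anchor with delays
#' chosen so that red cueing (neuron 1 at 0 ms, neuron 2 at 10 ms) yields
#' the firing order 3,4,5,6,7 and black cueing (neuron 2 at 0 ms, neuron 1
#' at 10 ms) yields 7,5,3,6,4.
#'
#' @return List with the \code{network}, the \code{red} and \code{black}
#'   templates (nominal patterns), and the synapse color labels
#'   (\code{color}, parallel to the synapse table).
#' @export
fixture_fig1_network <- function() {
  # Each subnetwork is a convergence chain: the anchors (n1, n2) drive the
  # first downstream neuron through a pair of strong synapses (weight 12;
  # two coincident arrivals fire a neuron, single arrivals or arrivals more
  # than ~3 ms apart do not), and every later neuron through three weight-8
  # synapses (three coincident arrivals needed), so only correctly timed
  # volleys propagate. Firing latency under threshold drive is 3 ms.
  lag <- 3L
  red_order <- c(3L, 4L, 5L, 6L, 7L)
  black_order <- c(7L, 5L, 3L, 6L, 4L)
  t_down <- c(15L, 19L, 23L, 27L, 31L)
  chain <- function(ord) {
    # anchor times: first anchor at 0, second at 10
    t_of <- c(`1` = NA, `2` = NA)
    pre <- integer(0); post <- integer(0); delay <- integer(0); w <- numeric(0)
    anchors <- if (identical(ord, red_order)) c(1L, 2L) else c(2L, 1L)
    tms <- c(0L, 10L)
    all_t <- stats::setNames(c(tms, t_down), c(anchors, ord))
    for (k in seq_along(ord)) {
      tk <- t_down[k]
      pres <- if (k == 1) anchors else {
        # the two anchors while in delay range, then the chain predecessors
        cand <- c(anchors, ord[seq_len(k - 1)])
        ct <- all_t[as.character(cand)]
        cand <- cand[tk - lag - ct >= 1 & tk - lag - ct <= 20]
        utils::tail(cand, 3)
      }
      pt <- all_t[as.character(pres)]
      pre <- c(pre, pres); post <- c(post, rep.int(ord[k], length(pres)))
      delay <- c(delay, tk - lag - pt)
      w <- c(w, rep.int(if (k == 1) 12 else 8, length(pres)))
    }
    data.frame(pre = pre, post = post, delay = as.integer(delay), weight = w)
  }
  red_syn <- chain(red_order)
  black_syn <- chain(black_order)
  tab <- rbind(red_syn, black_syn)
  color <- rep(c("red", "black"), c(nrow(red_syn), nrow(black_syn)))
  cfg <- network_config(n_neurons = 7, excitatory_fraction = 1,
                        connection_prob = 0.5, w_max = 12, mini_rate = 0)
  rs <- neuron_params("RS")
  o <- order(tab$pre)
  net <- list(n = 7L, exc = rep(TRUE, 7),
              params = list(a = rep(rs$a, 7), b = rep(rs$b, 7),
                            c = rep(rs$c, 7), d = rep(rs$d, 7)),
              syn = list(pre = tab$pre[o], post = tab$post[o],
                         delay = tab$delay[o], weight = tab$weight[o],
                         sd = numeric(nrow(tab)),
                         plastic = rep(TRUE, nrow(tab))),
              config = cfg, seed = 0L)
  class(net) <- "polywm_network"
  red <- png_template(c(1L, 2L, red_order), c(0, 10, t_down),
                      anchors = c(1L, 2L), id = 1L)
  black <- png_template(c(2L, 1L, black_order), c(0, 10, t_down),
                        anchors = c(2L, 1L), id = 2L)
  list(network = net, red = red, black = black, color = color[o])
}

#' Write a run manifest
#'
#' Records everything needed to re-run a command bit-identically: the
#' command, seed, configuration echo, package version and output paths.
#'
#' @param path Output file.
#' @param command Command name.
#' @param seed Integer seed.
#' @param config Named list echoed into the manifest.
#' @param outputs Character vector of output paths.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, command, seed, config = list(),
                           outputs = character(0)) {
  lines <- c("# polywm run manifest v1",
             paste0("command: ", command),
             paste0("seed: ", seed),
             paste0("package_version: ", as.character(utils::packageVersion("polywm"))),
             paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             unlist(lapply(names(config), function(k)
               paste0("config.", k, ": ", paste(config[[k]], collapse = " ")))),
             paste0("output: ", outputs))
  writeLines(lines, path)
  invisible(path)
}
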