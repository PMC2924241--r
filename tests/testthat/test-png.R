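test_that("templates normalize times and validate anchors", {
  tpl <- png_template(c(5, 3, 9), c(20, 10, 35), anchors = c(3, 5), id = 7L)
  expect_equal(tpl$time, c(0, 10, 25))
  expect_equal(tpl$neuron, c(3, 5, 9))
  expect_equal(tpl$size, 3)
  expect_equal(tpl$duration, 25)
  expect_error(png_template(1:3, 1:3, anchors = 4), "anchors")
})

test_that("the seven-neuron toy produces both polychronous orders", {
  fx <- fixture_fig1_network()
  red <- simulate_template(fx$network, data.frame(neuron = c(1, 2),
                                                  time = c(0, 10)),
                           min_size = 4)
  down <- red$neuron[!(red$neuron %in% c(1, 2))]
  expect_equal(down, c(3, 4, 5, 6, 7))
  black <- simulate_template(fx$network, data.frame(neuron = c(2, 1),
                                                    time = c(0, 10)),
                             min_size = 4)
  down_b <- black$neuron[!(black$neuron %in% c(1, 2))]
  expect_equal(down_b, c(7, 5, 3, 6, 4))
  # mistimed anchors: the cascade dies
  expect_null(simulate_template(fx$network,
                                data.frame(neuron = c(1, 2), time = c(0, 0)),
                                min_size = 4))
  expect_null(simulate_template(fx$network,
                                data.frame(neuron = c(1, 2), time = c(0, 30)),
                                min_size = 4))
})

test_that("discovery on the toy recovers exactly the red and black groups", {
  fx <- fixture_fig1_network()
  found <- find_pngs(fx$network, anchor_count = 2, min_size = 4,
                     max_sets_per_target = 50)
  expect_length(found, 2)
  downs <- lapply(found, function(t) t$neuron[!(t$neuron %in% c(1, 2))])
  expect_true(any(vapply(downs, identical, logical(1), c(3L, 4L, 5L, 6L, 7L))))
  expect_true(any(vapply(downs, identical, logical(1), c(7L, 5L, 3L, 6L, 4L))))
  # all-weights-zero network: nothing to discover
  dead <- fx$network
  dead$syn$weight[] <- 0
  expect_length(find_pngs(dead, anchor_count = 2, min_size = 4), 0)
})

test_that("discovery matches brute-force template enumeration on the toy", {
  fx <- fixture_fig1_network()
  net <- fx$network
  syn <- net$syn
  # brute force: every pair of distinct-pre strong synapses converging on a
  # common target, fired so the arrivals coincide
  combos <- list()
  for (j in sort(unique(syn$post))) {
    s <- which(syn$post == j & syn$weight >= 0.95 * net$config$w_max)
    if (length(s) < 2) next
    for (a in seq_along(s)) for (b in seq_len(a - 1)) {
      combos[[length(combos) + 1]] <- c(s[a], s[b])
    }
  }
  brute <- list()
  for (cmb in combos) {
    if (syn$pre[cmb[1]] == syn$pre[cmb[2]]) next
    d <- syn$delay[cmb]
    tpl <- simulate_template(net, data.frame(neuron = syn$pre[cmb],
                                             time = max(d) - d), min_size = 4)
    if (is.null(tpl)) next
    dup <- any(vapply(brute, function(x)
      polywm:::template_overlap_frac(tpl, x) >= 0.9, logical(1)))
    if (!dup) brute[[length(brute) + 1]] <- tpl
  }
  found <- find_pngs(net, anchor_count = 2, min_size = 4,
                     max_sets_per_target = 50)
  expect_equal(length(found), length(brute))
  key <- function(t) paste(t$neuron, round(t$time), collapse = ";")
  expect_setequal(vapply(found, key, ""), vapply(brute, key, ""))
})

test_that("inserted groups have the required convergent structure", {
  ins <- wm_fixture()
  net <- ins$network
  expect_length(ins$templates, 100)
  for (tpl in ins$templates[c(1, 50, 100)]) {
    expect_equal(tpl$size, 40)
    expect_equal(tpl$duration, 200)
    members <- unique(tpl$neuron)
    anchors <- tpl$anchors
    for (k in setdiff(members, anchors)) {
      aff <- which(net$syn$post == k & net$syn$pre %in% members &
                     net$syn$weight >= net$config$w_max)
      # arrivals of intra-group afferents must coincide at one time
      tk <- tpl$time[match(k, tpl$neuron)]
      tp <- tpl$time[match(net$syn$pre[aff], tpl$neuron)]
      arr <- tp + net$syn$delay[aff]
      arr <- arr[tp < tk]           # intra-group, earlier members only
      expect_gte(max(table(arr)), 3)
    }
  }
})

test_that("insertion is sound: anchor firing reproduces the inserted pattern", {
  ins <- wm_fixture()
  tpl <- ins$templates[[3]]
  anch <- data.frame(neuron = tpl$anchors,
                     time = tpl$time[match(tpl$anchors, tpl$neuron)])
  real <- simulate_template(ins$network, anch, min_size = 10)
  expect_false(is.null(real))
  matched <- vapply(seq_along(tpl$neuron), function(k)
    any(real$neuron == tpl$neuron[k] &
          abs(real$time - tpl$time[k]) <= 2), logical(1))
  expect_gte(mean(matched), 0.9)
})

test_that("infeasible insertion geometry is rejected", {
  net <- build_network(network_config(n_neurons = 200), seed = 1)
  # 10 neurons over 900 ms: gaps of 100 ms cannot be delay-matched
  expect_error(insert_pngs(net, n_groups = 1, size = 10, duration = 900),
               "infeasible")
})

test_that("detection finds a planted template and respects the threshold", {
  ins <- wm_fixture()
  tpl <- ins$templates[[1]]
  base <- data.frame(time = tpl$time + 1000, neuron = tpl$neuron)
  ev <- detect_activations(base, tpl)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$fraction, 1)
  expect_equal(ev$onset, 1000)
  # all spikes shifted +4 ms: still within the ±5 ms jitter
  ev4 <- detect_activations(data.frame(time = base$time + 4,
                                       neuron = base$neuron), tpl)
  expect_equal(nrow(ev4), 1)
  # 9 of 40 neurons on time (22.5%) is below the strict 25% threshold
  part <- base[seq_len(9), ]
  expect_equal(nrow(detect_activations(part, tpl)), 0)
  # 11 of 40 (27.5%) is above it
  part2 <- base[seq_len(11), ]
  expect_equal(nrow(detect_activations(part2, tpl)), 1)
  # empty raster
  expect_equal(nrow(detect_activations(base[0, ], tpl)), 0)
})

test_that("detection is monotone in threshold and jitter", {
  trial <- wm_trial_fixture()
  tpl <- trial$templates[[1]]
  r <- trial$raster
  n_base <- nrow(detect_activations(r, tpl, min_fraction = 0.25, jitter = 5))
  expect_gt(n_base, 0)
  for (f in c(0.4, 0.6)) {
    expect_lte(nrow(detect_activations(r, tpl, min_fraction = f, jitter = 5)),
               n_base)
  }
  for (j in c(3, 1)) {
    expect_lte(nrow(detect_activations(r, tpl, min_fraction = 0.25, jitter = j)),
               n_base)
  }
  # nested: tighter jitter AND higher threshold never beats either alone
  tight <- nrow(detect_activations(r, tpl, min_fraction = 0.5, jitter = 2))
  expect_lte(tight, nrow(detect_activations(r, tpl, min_fraction = 0.5, jitter = 5)))
})

test_that("the time-reversed surrogate preserves counts and is an involution", {
  set.seed(12)
  r <- data.frame(time = sort(runif(500, 0, 5000)),
                  neuron = sample(1:50, 500, replace = TRUE))
  s <- surrogate_raster(r, duration = 5000)
  expect_equal(nrow(s), nrow(r))
  expect_equal(table(s$neuron), table(r$neuron))
  rr <- surrogate_raster(s, duration = 5000)
  expect_equal(rr$time, sort(r$time))
  expect_equal(sum(rr$neuron), sum(r$neuron))
})

test_that("template detection on surrogate data is far below the real rate", {
  trial <- wm_trial_fixture()
  tpl <- trial$templates[[1]]
  real <- nrow(detect_activations(trial$raster, tpl))
  surr <- nrow(detect_activations(surrogate_raster(trial$raster,
                                                   trial$duration), tpl))
  expect_gt(real, 10)
  expect_lt(surr, real / 5)
})

test_that("group statistics are internally consistent", {
  a <- png_template(1:10, seq(0, 90, by = 10), id = 1L)
  b <- png_template(11:20, seq(0, 45, by = 5), id = 2L)
  c <- png_template(c(5:14), seq(0, 90, by = 10), id = 3L)
  st <- png_statistics(list(a, b, c), n_neurons = 30)
  expect_equal(st$count, 3)
  expect_equal(st$pair_overlap[1, 2], 0)      # disjoint
  expect_equal(st$pair_overlap[1, 3], 6)      # 5..10 shared
  expect_equal(st$pair_overlap[2, 3], 4)      # 11..14 shared
  expect_equal(sum(st$membership), sum(st$sizes))
  expect_equal(mean(st$durations), (90 + 45 + 90) / 3)
})

test_that("templates round-trip through the text format", {
  fx <- fixture_fig1_network()
  path <- tempfile(fileext = ".txt")
  write_templates(list(fx$red, fx$black), path)
  back <- read_templates(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$neuron, fx$red$neuron)
  expect_equal(back[[1]]$time, fx$red$time)
  expect_equal(back[[1]]$anchors, fx$red$anchors)
  expect_equal(back[[2]]$id, fx$black$id)
})
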