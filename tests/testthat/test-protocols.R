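test_that("cue protocols expand into the right stimulus events", {
  ins <- wm_fixture()
  tpl <- ins$templates[[1]]
  stim <- cue_png(tpl, cue_protocol())
  # 10 presentations of the first 80% of 40 events
  expect_equal(nrow(stim), 10 * ceiling(0.8 * 40))
  expect_equal(min(stim$time), 0)
  expect_equal(length(unique(stim$neuron)), 32)
  # presentations start every window/repetitions ms
  starts <- sort(unique(stim$time[stim$neuron == tpl$neuron[1]]))
  expect_equal(diff(starts), rep(100, 9))
  # a 10% segment only touches the first 4 events
  stim10 <- cue_png(tpl, cue_protocol(segment_fraction = 0.1))
  expect_equal(length(unique(stim10$neuron)), 4)
  expect_true(all(stim10$neuron %in% tpl$neuron[1:4]))
  # zero response probability: no events at all
  set.seed(1)
  expect_equal(nrow(cue_png(tpl, cue_protocol(response_probability = 0))), 0)
  # response probability thins events binomially
  set.seed(2)
  thin <- cue_png(tpl, cue_protocol(response_probability = 0.8))
  expect_lt(nrow(thin), 320)
  expect_gt(nrow(thin), 320 * 0.8 - 3 * sqrt(320 * 0.16))
})

test_that("activating one toy subnetwork potentiates only its synapses", {
  fx <- fixture_fig1_network()
  # drive the red firing order repeatedly with forced spikes
  red <- fx$red
  forced <- do.call(rbind, lapply(seq(0, 4500, by = 500), function(t0)
    data.frame(time = t0 + red$time, neuron = red$neuron)))
  out <- simulate(fx$network, 5000, forced = forced, mini_rate = 0,
                  plasticity = plasticity_config(), seed = 3)
  sd_red <- out$network$syn$sd[fx$color == "red"]
  sd_black <- out$network$syn$sd[fx$color == "black"]
  expect_gt(mean(sd_red), 0.5)
  # black synapses see incidental pre/post pairings of both signs during
  # red activity; the net change that would bias the black pattern stays
  # below a tenth of the red potentiation
  expect_lt(abs(mean(sd_black)), 0.1 * mean(sd_red))
})

test_that("a cued group is maintained and its trace behaves as expected", {
  trial <- wm_trial_fixture()
  ev <- trial$activations[[1]]
  verdict <- wm_maintained(ev, trial$cue_offset, trial$duration)
  expect_true(verdict$maintained)
  # the short-term trace of intra-group synapses dominates the rest
  tr <- trial$sd_trace
  late <- tr$time > 2000
  expect_gt(mean(tr$subset[late]), 0.15)
  expect_gt(mean(tr$subset[late]), 3 * abs(mean(tr$other[late])))
})

test_that("maintenance requires replay: erasing short-term increments kills it", {
  ins <- wm_fixture()
  tpl <- ins$templates[[1]]
  # suppress short-term increments from 5 s; sd then follows pure decay and
  # reactivations stop within ~3 decay constants
  trial <- run_wm_trial(ins$network, tpl, duration_ms = 24000,
                        gain_schedule = erase_wm(5000), seed = 201)
  ev <- trial$activations[[1]]
  expect_equal(sum(ev$onset > 5000 + 3 * 5000), 0)
  # the trace decays monotonically (up to sampling noise) after the fade
  tr <- trial$sd_trace
  post <- tr$subset[tr$time > 6000 & tr$time < 20000]
  expect_lt(mean(diff(post) > 1e-3), 0.05)
  # restoring the gain immediately is a no-op: maintenance continues
  trial2 <- run_wm_trial(ins$network, tpl, duration_ms = 15000,
                         gain_schedule = erase_wm(5000, restore_time = 5000),
                         seed = 201)
  expect_gt(sum(trial2$activations[[1]]$onset > 5000), 0)
})

test_that("erase schedules are well-formed", {
  sched <- erase_wm(5000)
  expect_equal(sched$st_gain, 0)
  expect_equal(sched$lt_gain, 1)
  sched2 <- erase_wm(5000, restore_time = 8000)
  expect_equal(sched2$st_gain, c(0, 1))
  expect_error(erase_wm(5000, restore_time = 4000), "restore_time")
})

test_that("an elevated neuromodulator lets three presentations suffice", {
  ins <- wm_fixture()
  offset_of <- function(tpl) 300 + tpl$duration
  # ignition after so brief a cue is stochastic: compare paired runs (same
  # seed, gain 5 vs gain 1) over three seeds
  hi <- lo <- logical(3)
  for (k in 1:3) {
    tpl <- ins$templates[[k]]
    h <- neuromodulator_cue(ins$network, tpl, presentations = 3, gain = 5,
                            duration_ms = 13000, seed = 202 + k)
    l <- neuromodulator_cue(ins$network, tpl, presentations = 3, gain = 1,
                            duration_ms = 13000, seed = 202 + k)
    hi[k] <- wm_maintained(h$activations[[1]], offset_of(tpl), 13000)$maintained
    lo[k] <- wm_maintained(l$activations[[1]], offset_of(tpl), 13000)$maintained
  }
  expect_gte(sum(hi), 1)
  expect_equal(sum(lo), 0)
  # no presentations at all: nothing to maintain
  none <- neuromodulator_cue(ins$network, ins$templates[[1]],
                             presentations = 0, gain = 5,
                             duration_ms = 6000, seed = 203)
  expect_equal(nrow(none$activations[[1]]), 0)
})

test_that("NMDA-mode maintenance is cue-dependent", {
  ins <- wm_fixture()
  tpl <- ins$templates[[5]]
  pl <- plasticity_config(shortterm_mode = "nmda")
  # without a cue the template is essentially never detected
  base <- simulate(ins$network, 15000, plasticity = pl, seed = 301)
  expect_lt(nrow(detect_activations(base$raster, tpl)), 3)
  cued <- run_wm_trial(ins$network, tpl, duration_ms = 15000,
                       plasticity = pl, seed = 204)
  ev <- cued$activations[[1]]
  expect_gt(nrow(ev), 10)
  expect_true(wm_maintained(ev, cued$cue_offset, 15000)$maintained)
})
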