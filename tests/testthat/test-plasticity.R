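cfg_lt <- plasticity_config(longterm_on = TRUE)

test_that("a single pre-then-post pair changes the weight by the window value", {
  st <- new_longterm_state(w = 1)
  st <- longterm_update(st, "pre", t = 100, cfg_lt)
  st <- longterm_update(st, "post", t = 105, cfg_lt)
  expect_equal(st$delta, 0.1 * exp(-5 / 20))
  # post-then-pre depresses
  st2 <- new_longterm_state(w = 1)
  st2 <- longterm_update(st2, "post", t = 100, cfg_lt)
  st2 <- longterm_update(st2, "pre", t = 107, cfg_lt)
  expect_equal(st2$delta, -0.12 * exp(-7 / 20))
})

test_that("weights are clipped to the configured bounds", {
  st <- new_longterm_state(w = 8)
  st <- longterm_update(st, "pre", t = 0, cfg_lt)
  st <- longterm_update(st, "post", t = 1, cfg_lt)
  expect_equal(st$w, 8)
  st <- new_longterm_state(w = 0.01)
  st <- longterm_update(st, "post", t = 0, cfg_lt)
  st <- longterm_update(st, "pre", t = 1, cfg_lt)
  expect_equal(st$w, 0)
})

test_that("repeated optimal pairs accumulate to w_max in the predicted count", {
  # widely spaced pairs: each adds A_plus * exp(-1/tau); geometric oracle
  per_pair <- 0.1 * exp(-1 / 20)
  n_pairs <- ceiling(8 / per_pair)
  st <- new_longterm_state(w = 0)
  t <- 0
  for (k in seq_len(n_pairs)) {
    st <- longterm_update(st, "pre", t, cfg_lt)
    st <- longterm_update(st, "post", t + 1, cfg_lt)
    t <- t + 500
  }
  expect_equal(st$w, 8)
  # one pair fewer stays strictly below the bound
  st <- new_longterm_state(w = 0)
  t <- 0
  for (k in seq_len(n_pairs - 1)) {
    st <- longterm_update(st, "pre", t, cfg_lt)
    st <- longterm_update(st, "post", t + 1, cfg_lt)
    t <- t + 500
  }
  expect_lt(st$w, 8)
})

test_that("sd decays toward zero with the 5 s time constant", {
  cfg <- plasticity_config()
  st <- new_shortterm_state(sd = 0.8)
  st <- shortterm_update(st, "none", t = 5000, cfg)
  expect_equal(st$sd, 0.8 * exp(-1))
  # halving time tau*ln(2) within 1%
  st <- new_shortterm_state(sd = 0.8)
  st <- shortterm_update(st, "none", t = 5000 * log(2), cfg)
  expect_equal(st$sd, 0.4, tolerance = 0.01)
})

test_that("a saturating optimal train pins sd at the +100% ceiling", {
  cfg <- plasticity_config()
  st <- new_shortterm_state()
  t <- 0
  for (k in 1:1000) {
    st <- shortterm_update(st, "pre", t, cfg)
    st <- shortterm_update(st, "post", t + 1, cfg)
    t <- t + 20
  }
  expect_equal(st$sd, 1)
  expect_equal(effective_weight(8, st), 16)
})

test_that("a post-then-pre pair depresses sd below its prior value", {
  cfg <- plasticity_config()
  st <- new_shortterm_state(sd = 0.5)
  st <- shortterm_update(st, "post", t = 0, cfg)
  st <- shortterm_update(st, "pre", t = 5, cfg)
  expect_lt(st$sd, 0.5)
  expect_gte(st$sd, cfg$sd_min)
})

test_that("pre-only or post-only activity leaves the short-term state unchanged", {
  cfg <- plasticity_config()
  for (kind in c("pre", "post")) {
    st <- new_shortterm_state()
    for (t in seq(0, 2000, by = 50)) st <- shortterm_update(st, kind, t, cfg)
    expect_equal(st$sd, 0)
  }
  # NMDA mode: pre-only never enters the up-state
  st <- new_nmda_state()
  cfgn <- plasticity_config(shortterm_mode = "nmda")
  for (t in seq(0, 2000, by = 10))
    st <- nmda_update(st, pre_arrival = TRUE, post_spike = FALSE, t, cfgn)
  expect_false(st$upstate)
  expect_equal(st$multiplier, 1)
})

test_that("incremental short-term updates match the all-pairs closed form", {
  cfg <- plasticity_config()
  set.seed(8)
  for (rep in 1:20) {
    n_ev <- sample(3:25, 1)
    events <- data.frame(time = sort(sample(0:5000, n_ev)),
                         type = sample(c("pre", "post"), n_ev, replace = TRUE))
    st <- new_shortterm_state()
    for (i in seq_len(nrow(events)))
      st <- shortterm_update(st, events$type[i], events$time[i], cfg)
    ref <- reference_shortterm(events, cfg)
    expect_equal(st$sd, ref$sd, tolerance = 1e-10)
    expect_true(st$sd >= cfg$sd_min && st$sd <= 1)
  }
})

test_that("NMDA hysteresis: up-state needs a coincident post spike and survives gaps", {
  cfg <- plasticity_config(shortterm_mode = "nmda")
  st <- new_nmda_state()
  # three arrivals within one tau exceed theta_up
  for (t in c(0, 10, 20)) st <- nmda_update(st, TRUE, FALSE, t, cfg)
  expect_gt(st$g, cfg$theta_up)
  expect_false(st$upstate)          # no post spike yet
  st <- nmda_update(st, FALSE, TRUE, 21, cfg)
  expect_true(st$upstate)
  expect_equal(st$multiplier, cfg$nmda_gain)
  expect_equal(effective_weight(4, st, cfg), 40)
  # silence until g < theta_down exits the up-state
  t_exit <- 21 + cfg$tau_nmda * log(st$g / cfg$theta_down) + 1
  st <- nmda_update(st, FALSE, FALSE, t_exit, cfg)
  expect_false(st$upstate)
  expect_equal(st$multiplier, 1)
})

test_that("effective weight maps both short-term states correctly", {
  expect_equal(effective_weight(8, NULL), 8)
  expect_equal(effective_weight(8, list(sd = 0)), 8)
  expect_equal(effective_weight(8, list(sd = 1)), 16)
  expect_equal(effective_weight(4, list(upstate = TRUE)), 40)
  expect_equal(effective_weight(4, list(upstate = FALSE)), 4)
  expect_error(effective_weight(4, list(foo = 1)), "short")
})

test_that("boundedness holds under random event fuzzing", {
  cfg <- plasticity_config()
  cfgn <- plasticity_config(shortterm_mode = "nmda")
  set.seed(99)
  for (rep in 1:30) {
    st <- new_shortterm_state()
    lt <- new_longterm_state(w = runif(1, 0, 8))
    nm <- new_nmda_state()
    t <- 0
    for (k in 1:80) {
      t <- t + sample(0:200, 1)
      ev <- sample(c("pre", "post"), 1)
      st <- shortterm_update(st, ev, t, cfg)
      lt <- longterm_update(lt, ev, t, cfg_lt)
      nm <- nmda_update(nm, ev == "pre", ev == "post", t, cfgn)
      expect_true(st$sd >= cfg$sd_min && st$sd <= 1)
      expect_true(lt$w >= 0 && lt$w <= 8)
      expect_gte(nm$g, 0)
    }
  }
})

test_that("the dendritic compartment shows the two NMDA regimes", {
  pre <- seq(100, 800, by = 50)
  # presynaptic spikes alone: small EPSPs, no plateau
  ctrl <- nmda_compartment_demo(pre, numeric(0), duration_ms = 1200)
  expect_lt(max(ctrl$v), -50)
  # pre-then-post pairing (10 ms lag): sustained depolarized plateau
  paired <- nmda_compartment_demo(pre, pre + 10, duration_ms = 1200)
  late <- paired$v[paired$time > 600 & paired$time < 800]
  expect_gt(mean(late), -40)
  # ratio of NMDA to AMPA current at full depolarization
  expect_equal(nmda_ampa_ratio(), 9)
})
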