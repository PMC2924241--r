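test_that("multiunit rate normalizes by bin width and subset size", {
  # 100 neurons, 100 spikes uniform over 1 s -> flat 1 Hz
  r <- data.frame(time = seq(5, 995, by = 10), neuron = rep(1:100))
  rc <- multiunit_rate(r, 1:100, bin_ms = 100, duration = 1000)
  expect_equal(rc$rate, rep(1, 10))
  # empty raster -> all-zero curve
  rc0 <- multiunit_rate(r[0, ], 1:100, bin_ms = 100, duration = 1000)
  expect_equal(rc0$rate, rep(0, 10))
  expect_error(multiunit_rate(r, integer(0)), "nonempty")
  # rate conservation: sum(rate * width * size) = spike count
  set.seed(3)
  r2 <- data.frame(time = runif(700, 0, 3000), neuron = sample(1:20, 700, TRUE))
  rc2 <- multiunit_rate(r2, 1:20, bin_ms = 250, duration = 3000)
  expect_equal(sum(rc2$rate * 0.25 * 20), 700)
})

test_that("CV follows its definition and known limits", {
  expect_equal(isi_cv(seq(0, 1000, by = 10)), 0)
  # ISIs {10,20} repeating: sd/mean with denominator n-1
  train <- cumsum(c(0, rep(c(10, 20), 50)))
  isis <- diff(train)
  expect_equal(isi_cv(train), sd(isis) / mean(isis))
  expect_equal(isi_cv(train), 5 / 15, tolerance = 1e-2)
  # homogeneous Poisson: CV -> 1
  set.seed(7)
  pois <- cumsum(rexp(10000, rate = 0.1))
  expect_equal(isi_cv(pois), 1, tolerance = 0.05)
  expect_warning(out <- isi_cv(c(1, 2)), "undefined")
  expect_true(is.na(out))
})

test_that("CV2 follows its local pairwise definition", {
  expect_equal(isi_cv2(seq(0, 500, by = 5)), 0)
  # single ISI pair (10, 20): 2|20-10|/(20+10)
  expect_equal(isi_cv2(c(0, 10, 30)), 2 * 10 / 30)
  expect_warning(out <- isi_cv2(c(1, 2)), "undefined")
  expect_true(is.na(out))
  # stationary renewal train: CV and CV2 agree within sampling error
  set.seed(9)
  pois <- cumsum(rexp(20000, 0.1))
  expect_lt(abs(isi_cv(pois) - isi_cv2(pois)), 0.1)
})

test_that("rate-ramped trains inflate CV above CV2", {
  # piecewise-stationary Poisson: slow rate modulation inflates global CV
  set.seed(21)
  seg <- lapply(c(0.5, 4, 0.5, 4, 0.5), function(rate)
    cumsum(rexp(200, rate)))
  t0 <- 0
  train <- numeric(0)
  for (s in seg) {
    train <- c(train, t0 + s)
    t0 <- max(train)
  }
  expect_gt(isi_cv(train), isi_cv2(train))
})

test_that("cross-correlogram shows shifts, symmetry and independence", {
  set.seed(5)
  a <- sort(runif(800, 0, 60000))
  b <- a + 5
  cc <- cross_correlogram(a, b, max_lag = 50, bin = 1)
  expect_equal(cc$lag[which.max(cc$count)], 5.5)  # lag 5 lands in bin (4,5]+
  # symmetry: CCG(a,b) at lag l equals CCG(b,a) at -l
  cc_ab <- cross_correlogram(a, b, max_lag = 20, bin = 2)
  cc_ba <- cross_correlogram(b, a, max_lag = 20, bin = 2)
  expect_equal(cc_ab$count, rev(cc_ba$count))
  # independent trains: approximately flat
  b2 <- sort(runif(800, 0, 60000))
  cc2 <- cross_correlogram(a, b2, max_lag = 50, bin = 10)
  expect_lt(max(cc2$count) / max(1, mean(cc2$count)), 3)
})

test_that("working-memory duration takes the last post-offset event", {
  ev <- data.frame(onset = c(2000, 5000, 13000))
  expect_equal(wm_duration(ev, 1000), 12000)
  out <- wm_duration(ev[0, , drop = FALSE], 1000)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "no_events"))
  # events before the offset are ignored
  expect_equal(wm_duration(data.frame(onset = c(500, 900)), 1000) |>
                 as.numeric(), 0)
})

test_that("capacity curve aggregates per-load verdicts", {
  v <- list(`1` = c(TRUE), `2` = c(TRUE, FALSE), `4` = rep(FALSE, 4))
  cc <- capacity_curve(v)
  expect_equal(cc$load, c(1, 2, 4))
  expect_equal(cc$held, c(1, 1, 0))
  # repeats averaged
  v2 <- list(`2` = list(c(TRUE, TRUE), c(TRUE, FALSE)))
  expect_equal(capacity_curve(v2)$held, 1.5)
})

test_that("cv_stats summarizes per-neuron variability over a window", {
  set.seed(11)
  r <- data.frame(time = sort(runif(2000, 0, 20000)),
                  neuron = sample(1:5, 2000, TRUE))
  st <- cv_stats(r, 1:5)
  expect_equal(nrow(st), 5)
  expect_true(all(st$cv > 0))
  expect_true(all(st$cv2 >= 0 & st$cv2 <= 2))
  # window restriction drops spikes
  st2 <- cv_stats(r, 1:5, from = 0, to = 1000)
  expect_true(all(st2$n_spikes <= st$n_spikes))
})
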