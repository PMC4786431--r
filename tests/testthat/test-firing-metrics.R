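test_that("sliding-window rate matches hand-computed counts", {
  # spikes at 0, 50, 100, 390, 600 ms: best 400 ms window holds 4 spikes
  tr <- spike_train(c(0, 0.05, 0.1, 0.39, 0.6), t_start = 0, t_end = 1.2)
  expect_equal(max_firing_rate(tr, dt = 400), 4 / 0.4)
  rc <- windowed_rate(tr, dt = 400, step = 1)
  expect_equal(max(rc$rate), 10)
  # regular 100 Hz train spanning more than one window
  reg <- spike_train(seq(0, 1, by = 0.01), t_end = 1.5)
  expect_equal(max_firing_rate(reg, dt = 400), 100, tolerance = 0.026)
  # empty train
  empty <- spike_train(numeric(0), t_start = 0, t_end = 1)
  expect_equal(max_firing_rate(empty), 0)
  expect_true(all(windowed_rate(empty, dt = 400)$rate == 0))
  expect_error(windowed_rate(tr, dt = 400, t_range = c(0, 0.2)),
               "shorter than the window")
})

test_that("maximum firing rate equals the exhaustive-placement oracle", {
  for (s in 1:100) {
    tr <- random_train(n = sample(5:80, 1), t_end = 3, seed = s,
                       cluster = s %% 2 == 0)
    for (dt in c(100, 400)) {
      expect_equal(max_firing_rate(tr, dt = dt),
                   oracle_max_window_count(tr$times, dt / 1000) / (dt / 1000),
                   info = sprintf("seed %d dt %d", s, dt))
    }
  }
})

test_that("non-overlapping bin mode gives a 50 ms rate histogram", {
  tr <- spike_train(c(0.01, 0.02, 0.06, 0.11, 0.12, 0.13), t_end = 0.2)
  rc <- windowed_rate(tr, dt = 50, bins = TRUE, t_range = c(0, 0.2))
  expect_equal(rc$t, c(0, 0.05, 0.1, 0.15))
  expect_equal(rc$rate, c(2, 1, 3, 0) / 0.05)
})

test_that("time to max reports the earliest maximal window edge", {
  prot <- ir_protocol()   # onset 1 s
  # sustained burst starting at onset
  tr <- spike_train(1 + (0:128) / 128, protocol = prot, t_end = 3)
  expect_lt(abs(time_to_max(tr)), 5)
  # burst starting 650 ms after onset, longer than the window
  tr2 <- spike_train(1.65 + (0:128) / 128, protocol = prot, t_end = 3.5)
  expect_lt(abs(time_to_max(tr2) - 650), 5)
  # tie between two identical bursts: the earlier one is reported
  b <- c(0:40) / 128
  tr3 <- spike_train(c(1.2 + b, 2.2 + b), protocol = prot, t_end = 4)
  ttm <- time_to_max(tr3)
  expect_lt(ttm, 300)
  expect_error(time_to_max(spike_train(numeric(0), t_end = 2),
                           stim_onset = 1), "undefined")
})

test_that("Gaussian spike density matches the closed form and conserves mass", {
  # single spike: peak value 1/(sigma sqrt(2 pi)) at the spike time
  tr <- spike_train(1, t_start = 0, t_end = 2)
  d <- spike_density(tr, sigma = 25, grid_step = 0.5)
  s <- 0.025
  expect_equal(max(d$rate), 1 / (s * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(d$t[which.max(d$rate)], 1, tolerance = 5e-4)
  # two spikes 10 ms apart: curve equals the analytic two-Gaussian sum
  tr2 <- spike_train(c(1, 1.01), t_start = 0, t_end = 2)
  d2 <- spike_density(tr2, sigma = 25, grid_step = 0.5)
  expect_equal(d2$rate, dnorm(d2$t, 1, s) + dnorm(d2$t, 1.01, s),
               tolerance = 1e-9)
  # integral over a wide range equals the spike count to < 0.1%
  for (seed in c(2, 3)) {
    trr <- random_train(60, t_end = 3, seed = seed)
    dr <- spike_density(trr, sigma = 25, t_range = c(-0.5, 3.5),
                        grid_step = 1)
    integral <- sum(dr$rate) * 1e-3
    expect_lt(abs(integral - 60) / 60, 1e-3)
  }
  expect_error(spike_density(tr, sigma = 0), "positive")
})

test_that("rate derivative matches analytic derivatives", {
  tr <- spike_train(1, t_start = 0.5, t_end = 1.5)
  d <- spike_density(tr, sigma = 25, grid_step = 0.1)
  dv <- rate_derivative(d, dt_grid = NULL)
  s <- 0.025
  analytic <- -(dv$t - 1) / s^2 * dnorm(dv$t, 1, s)
  i <- dv$t > 0.6 & dv$t < 1.4
  expect_lt(max(abs(dv$d_rate[i] - analytic[i])),
            1e-3 * max(abs(analytic)))
  # constant curve: zero derivative; linear ramp: constant derivative
  const <- rate_curve(seq(0, 1, 0.001), rep(5, 1001), "rect_window", 400)
  expect_true(all(abs(rate_derivative(const)$d_rate) < 1e-9))
  ramp <- rate_curve(seq(0, 1, 0.001), seq(0, 10, length.out = 1001),
                     "rect_window", 400)
  expect_equal(range(rate_derivative(ramp)$d_rate), c(10, 10),
               tolerance = 1e-6)
})

test_that("total peak number counts well-separated bursts exactly", {
  # one continuous burst: a single rise
  one <- locked_burst_train(1, t0 = 1.05, spikes_per_burst = 30,
                            burst_rate = 40)
  expect_identical(total_peak_number(one, window = c(1, 2))$total_peak_number,
                   1L)
  # k well-separated bursts give k for k in 1..6
  for (k in 1:6) {
    trk <- locked_burst_train(k, t0 = 1.02, period = 0.16,
                              spikes_per_burst = 5, burst_rate = 100)
    pk <- total_peak_number(trk, window = c(1, 1 + k * 0.16))
    expect_identical(pk$total_peak_number, as.integer(k),
                     label = sprintf("k = %d bursts", k))
  }
  # no spikes in window: zero peaks
  silent <- spike_train(c(0.1, 0.2), t_end = 3)
  expect_identical(total_peak_number(silent,
                                     window = c(1, 2))$total_peak_number, 0L)
})

test_that("total peak number is invariant to uniform time translation", {
  tr <- locked_burst_train(3, t0 = 1.02, period = 0.2)
  base <- total_peak_number(tr, window = c(1, 1.6))$total_peak_number
  for (shift in c(-0.5, 0.25, 2)) {
    trs <- spike_train(tr$times + shift, t_start = tr$t_start + shift,
                       t_end = tr$t_end + shift)
    expect_identical(total_peak_number(trs,
                                       window = c(1, 1.6) + shift)$total_peak_number,
                     base)
  }
})

test_that("accepted peaks always exceed the configured threshold", {
  prot <- ir_protocol()
  for (s in 1:10) {
    tr <- simulate_spike_train(train_spec(baseline_rate = 2,
                                          evoked_rate = 60, us_events = 2,
                                          seed = s), prot)
    pk <- total_peak_number(tr)
    if (pk$total_peak_number > 0)
      expect_true(all(pk$peak_values > pk$threshold))
  }
})

test_that("frequency change is the during-minus-before rate difference", {
  prot <- stimulus_protocol("light_continuous", onset = 5, duration = 5,
                            power = 0.2)
  # silent before, 10 Hz during
  tr <- spike_train(seq(5.05, 9.95, by = 0.1), protocol = prot,
                    t_start = 0, t_end = 10)
  expect_equal(frequency_change(tr), 10)
  # identical rates: zero change
  tr2 <- spike_train(seq(0.05, 9.95, by = 0.1), protocol = prot,
                     t_start = 0, t_end = 10)
  expect_equal(frequency_change(tr2), 0)
  # Poisson 5 Hz before / 30 Hz during converges to +25 Hz
  deltas <- vapply(1:100, function(i) {
    spec <- train_spec(baseline_rate = 5, evoked_rate = 30, seed = i)
    frequency_change(simulate_spike_train(spec, prot, t_end = 10))
  }, numeric(1))
  expect_equal(mean(deltas), 25, tolerance = 0.06 * 25)
  # windows exceeding the record error out
  short <- spike_train(c(1, 2), protocol = prot, t_start = 0, t_end = 8)
  expect_error(frequency_change(short), "exceed the recording")
})
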