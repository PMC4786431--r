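test_that("spike-train generator is a pure function of spec and protocol", {
  prot <- ir_protocol()
  spec <- train_spec(baseline_rate = 3, evoked_rate = 50, us_events = 2,
                     seed = 11)
  a <- simulate_spike_train(spec, prot)
  b <- simulate_spike_train(spec, prot)
  expect_identical(a$times, b$times)
  c <- simulate_spike_train(train_spec(baseline_rate = 3, evoked_rate = 50,
                                       us_events = 2, seed = 12), prot)
  expect_false(identical(a$times, c$times))
})

test_that("zero rates give an empty train and negative rates error", {
  prot <- ir_protocol()
  tr <- simulate_spike_train(train_spec(baseline_rate = 0, evoked_rate = 0),
                             prot)
  expect_length(tr$times, 0L)
  expect_error(train_spec(baseline_rate = -1), "non-negative")
  expect_error(train_spec(evoked_rate = -5), "non-negative")
})

test_that("evoked spike counts match the Poisson law over repetitions", {
  prot <- ir_protocol()
  counts <- vapply(1:200, function(i) {
    tr <- simulate_spike_train(train_spec(baseline_rate = 0,
                                          evoked_rate = 100, seed = i), prot)
    length(tr$times)
  }, numeric(1))
  # mean of 200 Poisson(100) draws: 95% CI half-width 1.96 * 10 / sqrt(200)
  expect_lt(abs(mean(counts) - 100), 1.96 * 10 / sqrt(200))
  # dead-time thinning makes counts slightly sub-Poisson; the Fano factor
  # should still be of order (1 - rate * tau)^2 = 0.64
  expect_gt(var(counts), 30)
})

test_that("pulsed protocols confine evoked spikes to the on-phases", {
  prot <- pulsed_light_protocol(onset = 1, n_pulses = 5)
  tr <- simulate_spike_train(train_spec(baseline_rate = 0, evoked_rate = 80,
                                        seed = 4), prot)
  on <- stim_on_intervals(prot)
  in_on <- vapply(tr$times, function(s)
    any(s >= on[, 1] & s < on[, 2]), logical(1))
  expect_true(all(in_on))
})

test_that("embedded US triplets satisfy the detector's definition", {
  prot <- ir_protocol()
  for (k in 1:4) {
    tr <- simulate_spike_train(train_spec(baseline_rate = 0, evoked_rate = 0,
                                          us_events = k, seed = k), prot)
    ev <- detect_us(tr)
    expect_identical(nrow(ev), attr(tr, "us_truth") |> nrow())
    expect_equal(ev$first_spike, attr(tr, "us_truth")$first_spike)
    expect_true(all(ev$isi1_ms < 9))
    expect_true(all(ev$isi2_ms > 20))
  }
  # with background spikes the detector still finds at least the embedded ones
  tr <- simulate_spike_train(train_spec(baseline_rate = 2, evoked_rate = 40,
                                        us_events = 3, seed = 5), prot)
  expect_gte(nrow(detect_us(tr)), 3L)
})

test_that("voltage-trace construction carries exact ground truth", {
  prot <- ir_protocol()
  tr <- spike_train(seq(0.2, 2.0, by = 0.2), protocol = prot)
  vt <- simulate_voltage_trace(tr, noise_sd = 0, fs = 10000)
  det <- detect_spikes(vt, threshold = 0.5)
  expect_length(det$times, 10L)
  expect_equal(det$times, attr(vt, "peak_times"), tolerance = 1e-9)
  # empty train, no noise: all-zero trace
  vt0 <- simulate_voltage_trace(spike_train(numeric(0), protocol = prot),
                                noise_sd = 0)
  expect_true(all(vt0$samples == 0))
  # noise far below threshold: no detections
  vtn <- simulate_voltage_trace(spike_train(numeric(0), protocol = prot),
                                noise_sd = 0.01, seed = 2)
  expect_length(detect_spikes(vtn, threshold = 0.5)$times, 0L)
  # spikes closer than the template support are flagged as overlapping
  tro <- spike_train(c(0.5, 0.5015), protocol = prot)
  expect_true(attr(simulate_voltage_trace(tro, noise_sd = 0), "overlap"))
})

test_that("calibration generator inverts exactly without noise", {
  cal <- simulate_calibration_data(n = 12, noise_sd = 0)
  fit <- fit_arrhenius(cal)
  expect_equal(coef(fit), c(a = 2.306e-3, b = 5.2e-4), tolerance = 1e-10)
  cal2 <- simulate_calibration_data(n = 2, noise_sd = 0)
  expect_equal(coef(fit_arrhenius(cal2)), c(a = 2.306e-3, b = 5.2e-4),
               tolerance = 1e-10)
  expect_error(simulate_calibration_data(n = 1), "n >= 2")
  expect_error(simulate_calibration_data(b = 0), "nonzero")
})

test_that("coupled trials realize the specified monotone coupling", {
  trials <- simulate_coupled_trials(n_trials = 20, seed = 3, gain = 5,
                                    noise = 0)
  cnt <- vapply(trials, function(tr) nrow(detect_us(tr$train)), numeric(1))
  drp <- vapply(trials, function(tr) tr$dr_peak, numeric(1))
  expect_equal(drp, 5 * cnt, tolerance = 1e-8)
  expect_equal(spearman_cor(cnt, drp)$rho, 1)
})

test_that("fret stack generator emits consistent ground truth", {
  sp <- fret_stack_spec(shape = c(32, 32, 60), transient_amplitude = 20,
                        noise_sd = 0, seed = 7)
  pair <- simulate_fret_stack(sp, ir_protocol())
  # zero amplitude, zero noise: flat ratio
  sp0 <- fret_stack_spec(shape = c(32, 32, 60), transient_amplitude = 0,
                         noise_sd = 0, seed = 7)
  pair0 <- simulate_fret_stack(sp0, ir_protocol())
  expect_true(all(abs(pair0$truth$dr) < 1e-12))
  # mask is the one-pixel dilation of the skeleton
  expect_true(all(pair$truth$mask[pair$truth$skeleton]))
  # transient polarity: YFP up, CFP down on the arbor during the transient
  f_peak <- which.max(pair$truth$dr)
  px <- which(pair$truth$mask, arr.ind = TRUE)[1, ]
  expect_gt(pair$yfp[px[1], px[2], f_peak], pair$yfp[px[1], px[2], 1])
  expect_lt(pair$cfp[px[1], px[2], f_peak], pair$cfp[px[1], px[2], 1])
  expect_error(fret_stack_spec(transient_amplitude = -3), "non-negative")
})

test_that("rate depression thins firing after each pause when enabled", {
  prot <- ir_protocol()
  n_post <- function(dep) {
    mean(vapply(1:40, function(i) {
      spec <- train_spec(baseline_rate = 0, evoked_rate = 80, us_events = 1,
                        pause_duration = 100, depression = dep,
                        depression_span = 300, seed = i)
      tr <- simulate_spike_train(spec, prot)
      us <- attr(tr, "us_truth")
      t0 <- us$second_spike[1] + 0.1
      sum(tr$times > t0 & tr$times <= t0 + 0.3)
    }, numeric(1)))
  }
  expect_lt(n_post(0.9), n_post(0) * 0.8)
})
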