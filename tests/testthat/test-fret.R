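make_rect_pair <- function(nx = 40, ny = 40, nf = 10, lvl = 100,
                           rect = c(10, 17, 12, 19)) {
  cfp <- array(0, dim = c(nx, ny, nf))
  cfp[rect[1]:rect[2], rect[3]:rect[4], ] <- lvl
  image_stack_pair(cfp, cfp, (seq_len(nf) - 1) * 0.05)
}

test_that("mask construction recovers simple and synthetic geometry", {
  # bright constant rectangle on zero background
  pair <- make_rect_pair()
  m <- build_mask(pair)
  truth <- matrix(FALSE, 40, 40)
  truth[10:17, 12:19] <- TRUE
  expect_identical(m$mask, truth)
  # synthetic arbor with noise (SNR >= 5): >= 95% recall, <= 2% false alarms
  sp <- fret_stack_spec(shape = c(48, 48, 60), transient_amplitude = 20,
                        noise_sd = 60, seed = 21)   # arbor product >> noise
  ps <- simulate_fret_stack(sp, ir_protocol())
  ms <- build_mask(ps)
  expect_gte(mean(ms$mask[ps$truth$mask]), 0.95)
  expect_lte(mean(ms$mask[!ps$truth$mask]), 0.02)
  # degenerate inputs
  zero <- image_stack_pair(array(0, c(8, 8, 3)), array(0, c(8, 8, 3)),
                           c(0, 1, 2))
  expect_error(build_mask(zero), "all-zero")
  unif <- image_stack_pair(array(5, c(16, 16, 3)), array(5, c(16, 16, 3)),
                           c(0, 1, 2))
  expect_error(build_mask(unif), "no separable foreground")
})

test_that("ratio extraction is exact on constant and stepped channels", {
  prot <- ir_protocol(onset = 0.5, duration = 0.5)
  nf <- 40
  ft <- (seq_len(nf) - 1) * 0.05
  mask <- matrix(FALSE, 20, 20); mask[8:12, 8:12] <- TRUE
  # constant channels: identically zero ratio change
  cfp <- array(50, c(20, 20, nf))
  for (f in seq_len(nf)) cfp[, , f][mask] <- 400
  pair <- image_stack_pair(cfp, cfp, ft, protocol = prot)
  trc <- extract_ratio_trace(pair, c(1, 20, 1, 20), mask, baseline = 0.5)
  expect_true(all(abs(trc$dR) < 1e-9))
  # injected 30% ratio step after stimulus end
  yfp <- cfp
  step <- ft >= 1
  for (f in which(step)) yfp[, , f][mask] <- 50 + (400 - 50) * 1.30
  pair2 <- image_stack_pair(cfp, yfp, ft, protocol = prot)
  trc2 <- extract_ratio_trace(pair2, c(1, 20, 1, 20), mask, baseline = 0.5)
  expect_equal(dr_peak(trc2), 30, tolerance = 1e-9)
  # ROI entirely in background errors
  expect_error(extract_ratio_trace(pair, c(1, 4, 1, 4), mask,
                                   baseline = 0.5), "does not overlap")
  # common scaling of both channels leaves the ratio unchanged
  pair3 <- image_stack_pair(cfp * 3.7, yfp * 3.7, ft, protocol = prot)
  trc3 <- extract_ratio_trace(pair3, c(1, 20, 1, 20), mask, baseline = 0.5)
  expect_equal(trc3$dR, trc2$dR, tolerance = 1e-9)
})

test_that("peak ratio change averages the post-cessation window", {
  ft <- seq(0, 3, by = 0.05)
  # flat zero trace and constant 20% trace
  expect_equal(dr_peak(ratio_trace(ft, rep(0, length(ft)), stim_end = 2)), 0)
  expect_equal(dr_peak(ratio_trace(ft, rep(20, length(ft)), stim_end = 2)),
               20)
  # exponential decay: window average matches the discrete closed form
  a <- 40; tau <- 0.9; t0 <- 1.5
  dr <- ifelse(ft >= t0, a * exp(-(ft - t0) / tau), 0)
  trc <- ratio_trace(ft, dr, stim_end = t0)
  in_win <- ft >= t0 + 0.4 & ft <= t0 + 0.7
  expect_equal(dr_peak(trc), mean(a * exp(-(ft[in_win] - t0) / tau)))
  # insufficient coverage errors
  expect_error(dr_peak(ratio_trace(ft, dr, stim_end = 2.5)),
               "does not cover")
})

test_that("transient classification applies the strict 10% rule", {
  expect_true(classify_transient(12))
  expect_false(classify_transient(8))
  expect_false(classify_transient(10))   # strictly larger than
  expect_identical(classify_transient(c(5, 10.0001, 30)),
                   c(FALSE, TRUE, TRUE))
})

test_that("occurrence rates reproduce exact binomial intervals", {
  # 13 transients of 18 trials: 72.2%
  r <- occurrence_rate(c(rep(TRUE, 13), rep(FALSE, 5)))
  expect_equal(r$proportion, 100 * 13 / 18, tolerance = 1e-9)
  expect_equal(round(r$proportion, 1), 72.2)
  # 0 of 9: 0.0% with lower bound 0
  r0 <- occurrence_rate(rep(FALSE, 9))
  expect_equal(r0$proportion, 0)
  expect_equal(r0$ci_lower, 0)
  # endpoints match the beta-quantile construction
  for (k in c(0, 3, 13, 18)) {
    n <- 18
    ri <- occurrence_rate(c(rep(TRUE, k), rep(FALSE, n - k)))
    o <- oracle_clopper_pearson(k, n)
    expect_equal(ri$ci_lower, 100 * o[1], tolerance = 1e-9)
    expect_equal(ri$ci_upper, 100 * o[2], tolerance = 1e-9)
  }
  expect_error(occurrence_rate(logical(0)), "at least one")
})

test_that("end-to-end pipeline recovers injected transient amplitudes", {
  prot <- ir_protocol()
  for (amp in c(5, 15)) {
    sp <- fret_stack_spec(shape = c(40, 40, 70), transient_amplitude = amp,
                          noise_sd = 0, seed = 31 + amp)
    pair <- simulate_fret_stack(sp, prot)
    m <- build_mask(pair)
    d <- dr_peak(extract_ratio_trace(pair, c(1, 40, 1, 40), m))
    expect_equal(d, amp, tolerance = 1e-6)
    expect_identical(classify_transient(d), amp > 10)
  }
})

test_that("soma pixels follow slower kinetics than the dendrite", {
  sp <- fret_stack_spec(shape = c(40, 40, 70), transient_amplitude = 25,
                        noise_sd = 0, soma_center = c(20, 20),
                        soma_radius = 4, decay_tau = 0.8, soma_tau = 3,
                        seed = 8)
  pair <- simulate_fret_stack(sp, ir_protocol())
  late <- which(pair$frame_times >= 2.8)[1]
  # by late frames the slow soma transient retains more of its amplitude
  expect_gt(pair$truth$dr_soma[late] / max(pair$truth$dr_soma),
            pair$truth$dr[late] / max(pair$truth$dr))
})

test_that("photobleach baseline fits exclude irradiation dips", {
  tt <- seq(0, 30, by = 0.1)
  truth <- c(c0 = 30, a0 = 150, k0 = 0.08)
  v <- truth["c0"] + truth["a0"] * exp(-truth["k0"] * tt)
  # constant trace: zero decay rate
  b0 <- bleach_baseline(rep(7, 50), seq(0, 4.9, by = 0.1))
  expect_equal(unname(b0$coef["k"]), 0)
  # clean exponential: exact recovery
  b1 <- bleach_baseline(v, tt)
  expect_true(b1$converged)
  expect_equal(unname(b1$coef), unname(truth), tolerance = 1e-6)
  # dips during irradiation are ignored and quantified by residuals
  win <- matrix(c(8, 9, 20, 21), 2, 2, byrow = TRUE)
  v2 <- v
  dip <- (tt >= 8 & tt <= 9) | (tt >= 20 & tt <= 21)
  v2[dip] <- v2[dip] * 0.6
  b2 <- bleach_baseline(v2, tt, win)
  expect_equal(unname(b2$coef), unname(truth), tolerance = 1e-6)
  expect_equal(mean(b2$residuals[dip] / b2$fitted[dip]), -0.4,
               tolerance = 1e-6)
  # recovery: points outside irradiation sit on the fitted curve
  expect_lt(max(abs(b2$residuals[!dip])), 1e-6)
})
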