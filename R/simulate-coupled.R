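#' Simulate a coupled spike-train / calcium-response trial
#'
#' Generates one trial in which the peak FRET-ratio change grows linearly
#' with the unconventional-spike content of the spike train. The train
#' carries `k_us` embedded US triplets (on top of its Poisson background,
#' which can contribute chance triplets of its own), and the ratio trace is
#' built analytically so that the trial's representative ratio change
#' equals `gain` times the train's total US count under the standard
#' 9/20 ms definition, plus Gaussian noise. Sets of such trials let
#' correlation analyses (US count versus peak ratio change) be validated
#' against a known monotone coupling: at zero noise the coupling is exact
#' and the Spearman correlation is 1 by construction.
#'
#' @param k_us number of embedded US triplets.
#' @param gain ratio-change increment per US (% per US); `gain = 0`
#'   decouples the trace from the train.
#' @param noise s.d. of the Gaussian noise added to the trial's peak ratio
#'   change (%).
#' @param seed integer seed.
#' @param protocol a [stimulus_protocol()].
#' @param spec a [train_spec()] template; its `us_events` and `seed` are
#'   overridden.
#' @param definition the [us_definition()] defining the coupled US count.
#' @param decay_tau decay constant of the synthetic ratio transient (s).
#' @param trial_id trial label.
#' @return a list with `train` (a [spike_train()]), `trace` (a
#'   [ratio_trace()]), `dr_peak` (the trial's ground-truth peak ratio
#'   change, %), `n_us` (the US count the trace was coupled to) and
#'   `k_us` (the embedded count).
#' @export
simulate_coupled_trial <- function(k_us, gain = 5, noise = 0, seed = 1L,
                                   protocol = ir_protocol(),
                                   spec = train_spec(baseline_rate = 2,
                                                     evoked_rate = 60),
                                   definition = us_definition(),
                                   decay_tau = 1, trial_id = "trial1") {
  if (gain < 0) stop("`gain` must be non-negative")
  spec$us_events <- as.integer(k_us)
  spec$seed <- as.integer(seed)
  train <- simulate_spike_train(spec, protocol, trial_id = trial_id)
  n_us <- nrow(detect_us(train, definition))
  set.seed(seed + 1L)
  amp <- n_us * gain + stats::rnorm(1L, sd = noise)
  win <- stim_window(protocol)
  ft <- seq(0, win[2] + 1, by = 0.05)
  dr <- if (abs(amp) < 1e-12) numeric(length(ft))
        else fret_transient_course(ft, win[1], win[2], amp, decay_tau)
  trace <- ratio_trace(ft, dr, roi_id = trial_id, stim_end = win[2],
                       stim_onset = win[1])
  list(train = train, trace = trace, dr_peak = dr_peak(trace),
       n_us = n_us, k_us = k_us)
}

#' Simulate a set of coupled trials
#'
#' @param n_trials number of trials; embedded US counts cycle through
#'   `0:max_us`.
#' @param max_us largest embedded US count.
#' @param seed integer seed; trial i uses child seed `seed + 101 * i`.
#' @param ... passed to [simulate_coupled_trial()].
#' @return list of trials as returned by [simulate_coupled_trial()].
#' @export
simulate_coupled_trials <- function(n_trials = 20, max_us = 4, seed = 1L,
                                    ...) {
  lapply(seq_len(n_trials), function(i)
    simulate_coupled_trial(k_us = (i - 1L) %% (max_us + 1L),
                           seed = seed + 101L * i,
                           trial_id = sprintf("trial%02d", i), ...))
}
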