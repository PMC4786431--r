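#' Specification of a synthetic spike train
#'
#' Parameters of the phenomenological firing model used by
#' [simulate_spike_train()]: an inhomogeneous Poisson process at
#' `baseline_rate` outside the stimulus and `evoked_rate` during it (during
#' the on-phases only for pulsed protocols), with `us_events` unconventional
#' spike (US) triplets embedded in the stimulation window, each followed by
#' a silent pause.
#'
#' The embedded triplet reproduces the burst-and-pause signature: two spikes
#' separated by `us_isi1` ms (below the 9 ms bound of the US definition)
#' whose following interval — the pause — exceeds the 20 ms bound. The pause
#' duration has no published distribution and is a free parameter.
#'
#' @param baseline_rate firing rate outside the stimulus (Hz), >= 0.
#' @param evoked_rate firing rate during the stimulus (Hz), >= 0.
#' @param us_events number of US triplets to embed during the stimulus.
#' @param pause_duration silent pause after each embedded US (ms), >= 0.
#' @param us_isi1 first interspike interval of each embedded US (ms);
#'   deliberately shorter than the refractory floor of ordinary spikes —
#'   that is what makes the pair unconventional.
#' @param refractory dead time of ordinary firing (ms): spikes closer than
#'   this to their predecessor are thinned out, and the underlying Poisson
#'   intensity is compensated (lambda / (1 - lambda * tau)) so the realized
#'   rate still converges to the nominal one. Requires
#'   `rate * refractory < 1`. Embedded US pairs are exempt.
#' @param depression depth of the optional post-pause rate depression
#'   (fraction of the evoked rate suppressed immediately after each pause;
#'   0 disables it, the default).
#' @param depression_span span over which the depressed rate recovers
#'   linearly (ms).
#' @param seed integer seed; identical `(spec, protocol)` pairs give
#'   identical trains.
#'
#' @return an object of class `train_spec`.
#' @export
train_spec <- function(baseline_rate = 1, evoked_rate = 60, us_events = 0,
                       pause_duration = 150, us_isi1 = 5, refractory = 2,
                       depression = 0, depression_span = 200, seed = 1L) {
  if (baseline_rate < 0 || evoked_rate < 0)
    stop("firing rates must be non-negative")
  if (refractory < 0) stop("`refractory` must be non-negative (ms)")
  if (max(baseline_rate, evoked_rate) * refractory / 1000 >= 1)
    stop("rate * refractory must stay below 1 for the dead-time model")
  if (pause_duration < 0) stop("`pause_duration` must be non-negative")
  if (us_events < 0 || us_events != round(us_events))
    stop("`us_events` must be a non-negative integer")
  if (us_isi1 <= 0) stop("`us_isi1` must be positive (ms)")
  if (depression < 0 || depression > 1)
    stop("`depression` must be in [0, 1]")
  structure(list(baseline_rate = baseline_rate, evoked_rate = evoked_rate,
                 us_events = as.integer(us_events),
                 pause_duration = pause_duration, us_isi1 = us_isi1,
                 refractory = refractory,
                 depression = depression, depression_span = depression_span,
                 seed = as.integer(seed)),
            class = "train_spec")
}

# homogeneous Poisson spikes on [t0, t1) at `rate` Hz
rpoisson_spikes <- function(t0, t1, rate) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1L, rate * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

#' Simulate a spike train under a stimulus protocol
#'
#' Draws an inhomogeneous Poisson spike train whose rate steps between the
#' baseline and evoked values of `spec` according to `protocol`, then embeds
#' `us_events` unconventional-spike triplets inside the stimulation window.
#' Each embedded US replaces the Poisson spikes in its local window (rather
#' than superposing on them) so that the injected interspike-interval
#' pattern is guaranteed, and is followed by a hard silent pause of
#' `pause_duration` ms.
#'
#' @param spec a [train_spec()].
#' @param protocol a [stimulus_protocol()].
#' @param t_end end of the simulated recording (s); defaults to 1 s past the
#'   stimulus end.
#' @param trial_id trial label.
#'
#' @return a [spike_train()]. The ground-truth embedded US pairs are
#'   attached as `attr(, "us_truth")`, a data frame with columns
#'   `first_spike` and `second_spike` (s).
#' @export
simulate_spike_train <- function(spec, protocol, t_end = NULL,
                                 trial_id = "trial1") {
  stopifnot(inherits(spec, "train_spec"),
            inherits(protocol, "stimulus_protocol"))
  set.seed(spec$seed)
  win <- stim_window(protocol)
  if (is.null(t_end)) t_end <- win[2] + 1
  on <- stim_on_intervals(protocol)
  on[, 1] <- pmax(0, pmin(on[, 1], t_end))
  on[, 2] <- pmax(0, pmin(on[, 2], t_end))

  # segment [0, t_end) into evoked on-phases and baseline remainder;
  # Poisson intensity is compensated for the dead time applied below
  tau <- spec$refractory / 1000
  comp <- function(rate) if (rate > 0) rate / (1 - rate * tau) else 0
  spikes <- numeric(0)
  cursor <- 0
  for (k in seq_len(nrow(on))) {
    spikes <- c(spikes,
                rpoisson_spikes(cursor, on[k, 1], comp(spec$baseline_rate)),
                rpoisson_spikes(on[k, 1], on[k, 2], comp(spec$evoked_rate)))
    cursor <- on[k, 2]
  }
  spikes <- c(spikes, rpoisson_spikes(cursor, t_end, comp(spec$baseline_rate)))
  if (tau > 0 && length(spikes) > 1L) {
    keep <- rep(TRUE, length(spikes))
    last <- spikes[1]
    for (i in 2:length(spikes)) {
      if (spikes[i] - last < tau) keep[i] <- FALSE else last <- spikes[i]
    }
    spikes <- spikes[keep]
  }

  us_truth <- data.frame(first_spike = numeric(0), second_spike = numeric(0))
  if (spec$us_events > 0) {
    isi1 <- spec$us_isi1 / 1000
    pause <- spec$pause_duration / 1000
    footprint <- isi1 + pause
    k <- spec$us_events
    if (k * footprint > protocol$duration)
      stop("us_events do not fit in the stimulation window; ",
           "reduce `us_events` or `pause_duration`")
    # anchors spread evenly through the stimulation window
    anchors <- win[1] + (seq_len(k) - 0.5) / k * (protocol$duration - footprint)
    guard <- max(spec$refractory, 1) / 1000
    for (a in anchors) {
      keep <- spikes < a - guard | spikes > a + footprint
      spikes <- c(spikes[keep], a, a + isi1)
      if (spec$depression > 0) {
        # thin spikes in the recovery span after the pause
        t_rec0 <- a + footprint
        span <- spec$depression_span / 1000
        in_rec <- spikes > t_rec0 & spikes <= t_rec0 + span
        if (any(in_rec)) {
          p_keep <- 1 - spec$depression * (1 - (spikes[in_rec] - t_rec0) / span)
          drop <- in_rec
          drop[in_rec] <- stats::runif(sum(in_rec)) > p_keep
          spikes <- spikes[!drop]
        }
      }
      spikes <- sort(spikes)
      us_truth <- rbind(us_truth,
                        data.frame(first_spike = a, second_spike = a + isi1))
    }
    # firing resumes after each pause; make sure a successor spike exists so
    # every injected pair completes a triplet (matters when rates are 0)
    for (second in us_truth$second_spike) {
      resume <- second + pause + 0.005
      if (!any(spikes > second) && resume <= t_end)
        spikes <- sort(c(spikes, resume))
    }
  }
  spikes <- sort(unique(spikes))
  out <- spike_train(spikes, protocol = protocol, trial_id = trial_id,
                     t_start = 0, t_end = t_end)
  attr(out, "us_truth") <- us_truth
  out
}
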