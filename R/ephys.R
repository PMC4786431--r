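#' Uniformly sampled extracellular voltage trace
#'
#' @param samples voltage samples (arbitrary units, typically mV).
#' @param fs sampling rate (Hz), > 0.
#' @param t0 time of the first sample (s).
#' @return an object of class `voltage_trace`.
#' @export
voltage_trace <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive sampling rate (Hz)")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("voltage samples must be finite")
  structure(list(samples = samples, fs = fs, t0 = t0),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples @ %g kHz (%.3f s from t0 = %g s)\n",
              length(x$samples), x$fs / 1000, length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @export
plot.voltage_trace <- function(x, y, ...) {
  t <- x$t0 + (seq_along(x$samples) - 1L) / x$fs
  plot(t, x$samples, type = "l", xlab = "time (s)", ylab = "voltage", ...)
  invisible(x)
}

# sample times of a trace
trace_times <- function(trace) trace$t0 + (seq_along(trace$samples) - 1L) / trace$fs

#' Biphasic extracellular spike template
#'
#' One cycle of a Hann-windowed sine: a positive lobe followed by a negative
#' lobe, peaking a quarter of the way through its support.
#'
#' @param fs sampling rate (Hz).
#' @param width_ms template support (ms).
#' @param amplitude peak amplitude.
#' @return numeric vector of template samples; the index of the positive
#'   peak is attached as `attr(, "peak_index")`.
#' @export
biphasic_template <- function(fs, width_ms = 3, amplitude = 1) {
  n <- max(4L, round(fs * width_ms / 1000))
  ph <- seq(0, 1, length.out = n)
  w <- amplitude * sin(2 * pi * ph) * (0.5 - 0.5 * cos(2 * pi * ph))
  w <- w / max(w) * amplitude
  structure(w, peak_index = which.max(w))
}

#' Simulate an extracellular voltage trace from a spike train
#'
#' Superposes a spike waveform template at every spike time and adds iid
#' Gaussian noise, producing a fixture with exactly known ground truth for
#' the spike detector.
#'
#' @param train a [spike_train()].
#' @param waveform template samples (default [biphasic_template()]).
#' @param noise_sd Gaussian noise s.d. (same units as the template).
#' @param fs sampling rate (Hz); recordings are typically sampled at 10 or
#'   20 kHz.
#' @param seed integer seed for the noise.
#' @return a [voltage_trace()] spanning the recording extent of `train`.
#'   Ground-truth spike-peak times are attached as `attr(, "peak_times")`;
#'   if any two spikes are closer than the template support, the overlap is
#'   flagged in `attr(, "overlap")`.
#' @export
simulate_voltage_trace <- function(train, waveform = NULL, noise_sd = 0,
                                   fs = 10000, seed = 1L) {
  stopifnot(inherits(train, "spike_train"))
  if (!fs %in% c(10000, 20000))
    warning("fs is usually 10 or 20 kHz")
  if (is.null(waveform)) waveform <- biphasic_template(fs)
  set.seed(seed)
  n <- ceiling((train$t_end - train$t_start) * fs) + length(waveform)
  x <- numeric(n)
  idx <- round((train$times - train$t_start) * fs) + 1L
  for (i in idx) {
    j <- i:(i + length(waveform) - 1L)
    x[j] <- x[j] + waveform
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)
  out <- voltage_trace(x, fs = fs, t0 = train$t_start)
  pk <- attr(waveform, "peak_index")
  if (is.null(pk)) pk <- which.max(waveform)
  attr(out, "peak_times") <- train$t_start + (idx + pk - 2L) / fs
  attr(out, "overlap") <- length(idx) > 1L &&
    any(diff(idx) < length(waveform))
  out
}

#' Band-pass filter an extracellular voltage trace
#'
#' Cascade of a first-order RC high-pass (cutoff `hp_fc`, default 100 Hz)
#' and an 8-pole Butterworth low-pass (cutoff `lp_fc`, default 2 kHz), the
#' conditioning applied to extracellular recordings before spike
#' thresholding. The filter is applied forward-only (causal) by default;
#' `zero_phase = TRUE` applies each stage forward and backward instead.
#'
#' @param trace a [voltage_trace()].
#' @param hp_fc high-pass cutoff (Hz).
#' @param lp_fc low-pass cutoff (Hz).
#' @param zero_phase apply each filter stage in both directions
#'   (zero-phase), as offline analysis software does.
#' @return the filtered [voltage_trace()].
#' @export
bandpass_filter <- function(trace, hp_fc = 100, lp_fc = 2000,
                            zero_phase = FALSE) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (trace$fs <= 2 * lp_fc)
    stop("sampling rate must exceed twice the low-pass cutoff")
  hp <- signal::butter(1, hp_fc / (trace$fs / 2), type = "high")
  lp <- signal::butter(8, lp_fc / (trace$fs / 2), type = "low")
  apply1 <- function(f, x) {
    if (zero_phase) signal::filtfilt(f, x)
    else as.numeric(signal::filter(f, x))
  }
  y <- apply1(lp, apply1(hp, trace$samples))
  voltage_trace(y, fs = trace$fs, t0 = trace$t0)
}

#' Detect spikes by thresholding a filtered voltage trace
#'
#' Emits one spike per threshold crossing, timestamped at the local extremum
#' within 1 ms after the crossing. Crossings within the refractory window of
#' an accepted spike are ignored, which prevents the second lobe of a
#' biphasic waveform from being counted twice.
#'
#' @param trace a band-pass filtered [voltage_trace()].
#' @param threshold detection threshold (same units as the trace).
#' @param refractory dead time after each accepted spike (ms).
#' @param polarity `"positive"` detects upward crossings, `"negative"`
#'   downward ones.
#' @param protocol optional [stimulus_protocol()] attached to the result.
#' @param trial_id trial label.
#' @return a [spike_train()].
#' @export
detect_spikes <- function(trace, threshold, refractory = 2,
                          polarity = c("positive", "negative"),
                          protocol = NULL, trial_id = "trial1") {
  stopifnot(inherits(trace, "voltage_trace"))
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("`threshold` must be a single finite number")
  polarity <- match.arg(polarity)
  x <- trace$samples
  if (polarity == "negative") {
    x <- -x
    threshold <- -threshold
  }
  above <- x >= threshold
  crossings <- which(!above[-length(above)] & above[-1]) + 1L
  if (above[1]) crossings <- c(1L, crossings)
  peak_span <- max(1L, round(trace$fs / 1000))   # 1 ms search for extremum
  refr_n <- refractory / 1000 * trace$fs
  times <- numeric(0)
  last_idx <- -Inf
  for (cr in crossings) {
    if (cr - last_idx <= refr_n) next
    j <- cr:min(cr + peak_span, length(x))
    pk <- j[which.max(x[j])]
    times <- c(times, trace$t0 + (pk - 1L) / trace$fs)
    last_idx <- cr
  }
  spike_train(unique(times), protocol = protocol, trial_id = trial_id,
              t_start = trace$t0,
              t_end = trace$t0 + (length(x) - 1L) / trace$fs)
}

#' Align spike waveform snippets and average them
#'
#' Cuts a snippet around every anchor time, aligns them on the anchor sample
#' (anchors are spike-peak times, so snippets are peak-aligned), and returns
#' the pointwise mean and standard deviation, the mean +/- s.d. band used to
#' summarise spike waveforms.
#'
#' @param traces a [voltage_trace()] or a list of them.
#' @param anchors numeric vector of anchor times (s), or a list of vectors
#'   parallel to `traces`.
#' @param window `c(pre, post)` extent of each snippet around the anchor (ms).
#' @return a list with `t_rel` (ms, relative to the anchor), `mean`, `sd`
#'   (pointwise, `sd` is `NA` when only one snippet survives) and `n`
#'   (snippets used). Anchors too close to a trace edge are dropped with a
#'   warning.
#' @export
align_and_average <- function(traces, anchors, window = c(1, 2)) {
  if (inherits(traces, "voltage_trace")) traces <- list(traces)
  if (!is.list(anchors)) anchors <- list(anchors)
  stopifnot(length(traces) == length(anchors), length(window) == 2L)
  snippets <- list()
  dropped <- 0L
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    pre_n <- round(window[1] / 1000 * tr$fs)
    post_n <- round(window[2] / 1000 * tr$fs)
    for (a in anchors[[k]]) {
      i <- round((a - tr$t0) * tr$fs) + 1L
      if (i - pre_n < 1L || i + post_n > length(tr$samples)) {
        dropped <- dropped + 1L
        next
      }
      snippets[[length(snippets) + 1L]] <- tr$samples[(i - pre_n):(i + post_n)]
    }
  }
  if (dropped > 0L)
    warning(dropped, " anchor(s) too close to a trace edge; snippet(s) dropped")
  if (!length(snippets)) stop("no usable snippets")
  m <- do.call(rbind, snippets)
  fs <- traces[[1]]$fs
  t_rel <- (seq_len(ncol(m)) - 1L - round(window[1] / 1000 * fs)) / fs * 1000
  list(t_rel = t_rel,
       mean = colMeans(m),
       sd = if (nrow(m) > 1L) apply(m, 2L, stats::sd) else rep(NA_real_, ncol(m)),
       n = nrow(m))
}
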