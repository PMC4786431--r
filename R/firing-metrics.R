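#' Firing-rate curve
#'
#' Time-resolved firing rate estimated either by a sliding rectangular
#' window (`method = "rect_window"`, parameter: window width in ms) or by
#' Gaussian-kernel spike density estimation (`method = "gaussian_kernel"`,
#' parameter: kernel s.d. in ms).
#'
#' @param t time grid (s). For `rect_window`, times are the left edges of
#'   the window placements.
#' @param rate firing rate (Hz), non-negative.
#' @param method `"rect_window"` or `"gaussian_kernel"`.
#' @param param window width or kernel sigma (ms).
#' @return an object of class `rate_curve`.
#' @export
rate_curve <- function(t, rate, method = c("rect_window", "gaussian_kernel"),
                       param) {
  method <- match.arg(method)
  stopifnot(length(t) == length(rate), all(is.finite(t)), all(is.finite(rate)))
  if (any(rate < -1e-12)) stop("rates must be non-negative")
  structure(list(t = as.numeric(t), rate = pmax(0, as.numeric(rate)),
                 method = method, param = param),
            class = "rate_curve")
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("<rate_curve> %s (%g ms), %d points, max %.2f Hz\n",
              x$method, x$param, length(x$t),
              if (length(x$rate)) max(x$rate) else 0))
  invisible(x)
}

#' @export
plot.rate_curve <- function(x, y, ...) {
  plot(x$t, x$rate, type = "l", xlab = "time (s)", ylab = "rate (Hz)", ...)
  invisible(x)
}

#' Sliding rectangular-window firing rate
#'
#' Slides a rectangular window of width `dt` along the spike train; the
#' rate at left edge `t` is the spike count in the half-open window
#' `[t, t + dt)` divided by `dt`. With `bins = TRUE` the windows are
#' non-overlapping (a peristimulus-time histogram with `dt` bins).
#'
#' @param train a [spike_train()].
#' @param dt window width (ms); 400 ms is the conventional width for
#'   maximum-firing-rate analysis, 50 ms for rate histograms.
#' @param step placement step (ms); ignored when `bins = TRUE`.
#' @param t_range range of left-edge placements (s); defaults to the
#'   recording extent (the last placement keeps the window inside it).
#' @param bins use non-overlapping windows.
#' @return a [rate_curve()].
#' @export
windowed_rate <- function(train, dt = 400, step = 1, t_range = NULL,
                          bins = FALSE) {
  stopifnot(inherits(train, "spike_train"))
  if (dt <= 0) stop("`dt` must be positive")
  dts <- dt / 1000
  if (is.null(t_range)) t_range <- c(train$t_start, train$t_end)
  if (t_range[2] - t_range[1] < dts)
    stop("placement range shorter than the window")
  edges <- if (bins) seq(t_range[1], t_range[2] - dts, by = dts)
           else seq(t_range[1], t_range[2] - dts, by = step / 1000)
  cnt <- count_in_window(train$times, edges, edges + dts)
  rate_curve(edges, cnt / dts, "rect_window", dt)
}

#' Maximum firing rate of a trial
#'
#' The maximum of the sliding rectangular-window rate over all real-valued
#' window placements. Because the count in `[t, t + dt)` is maximal for
#' some placement whose left edge coincides with a spike, the exact maximum
#' is found by evaluating the window at every spike time.
#'
#' @inheritParams windowed_rate
#' @return maximum firing rate (Hz); 0 for an empty train.
#' @export
max_firing_rate <- function(train, dt = 400) {
  stopifnot(inherits(train, "spike_train"))
  if (dt <= 0) stop("`dt` must be positive")
  n <- length(train$times)
  if (n == 0L) return(0)
  dts <- dt / 1000
  cnt <- n_spikes_before(train$times, train$times + dts) - (seq_len(n) - 1L)
  max(cnt) / dts
}

#' Time to maximum firing rate
#'
#' The left edge, relative to the stimulus onset, of the earliest sliding
#' window that attains the maximum firing rate; the latency metric for
#' heat-evoked responses. Window placements are scanned on a regular grid
#' of `step` ms; ties are broken toward the earliest placement.
#'
#' @inheritParams windowed_rate
#' @param stim_onset stimulus onset (s); defaults to the train's protocol.
#' @return latency (ms, may be negative if the maximum precedes the onset).
#' @export
time_to_max <- function(train, dt = 400, stim_onset = NULL, step = 1) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$times) == 0L)
    stop("time_to_max is undefined for an empty train")
  if (is.null(stim_onset)) {
    if (is.null(train$protocol)) stop("`stim_onset` required (no protocol)")
    stim_onset <- train$protocol$onset
  }
  dts <- dt / 1000
  lo <- min(stim_onset, train$times[1] - dts)
  hi <- max(train$times[length(train$times)], stim_onset)
  edges <- seq(lo, hi, by = step / 1000)
  cnt <- count_in_window(train$times, edges, edges + dts)
  best <- edges[which.max(cnt)]   # which.max takes the earliest tie
  (best - stim_onset) * 1000
}

#' Gaussian-kernel spike density estimate
#'
#' Sum of unit-area Gaussian kernels centred at the spike times, evaluated
#' on a uniform grid. No boundary correction is applied, so kernel mass may
#' leak outside the evaluated range; over a range extending several sigma
#' beyond the spikes, the time integral of the curve equals the spike
#' count.
#'
#' @param train a [spike_train()].
#' @param sigma kernel standard deviation (ms); 25 ms is the conventional
#'   value for burst-peak analysis.
#' @param t_range evaluation range (s); defaults to the recording extent.
#' @param grid_step grid step (ms).
#' @return a [rate_curve()] with method `"gaussian_kernel"`.
#' @export
spike_density <- function(train, sigma = 25, t_range = NULL, grid_step = 1) {
  stopifnot(inherits(train, "spike_train"))
  if (sigma <= 0) stop("`sigma` must be positive")
  if (is.null(t_range)) t_range <- c(train$t_start, train$t_end)
  tg <- seq(t_range[1], t_range[2], by = grid_step / 1000)
  s <- sigma / 1000
  dens <- numeric(length(tg))
  # chunk the spikes so the outer product stays small
  times <- train$times
  for (i in seq_len(ceiling(length(times) / 256))) {
    sp <- times[((i - 1L) * 256L + 1L):min(i * 256L, length(times))]
    dens <- dens + rowSums(outer(tg, sp, function(a, b) stats::dnorm(a, b, s)))
  }
  rate_curve(tg, dens, "gaussian_kernel", sigma)
}

#' Time derivative of a rate curve
#'
#' Finite-difference time derivative, by default resampled onto a 0.1 ms
#' grid (linear interpolation of the input curve) so that derivative peaks
#' are localised finely. Central differences are used in the interior,
#' one-sided differences at the edges.
#'
#' @param curve a [rate_curve()].
#' @param dt_grid output grid step (ms); `NULL` keeps the input grid.
#' @return a list of class `rate_derivative` with elements `t` (s) and
#'   `d_rate` (Hz/s).
#' @export
rate_derivative <- function(curve, dt_grid = 0.1) {
  stopifnot(inherits(curve, "rate_curve"))
  t <- curve$t
  r <- curve$rate
  if (!is.null(dt_grid)) {
    tg <- seq(t[1], t[length(t)], by = dt_grid / 1000)
    r <- stats::approx(t, r, xout = tg)$y
    t <- tg
  }
  n <- length(t)
  if (n < 2L) stop("need at least two grid points")
  h <- t[2] - t[1]
  d <- numeric(n)
  d[1] <- (r[2] - r[1]) / h
  d[n] <- (r[n] - r[n - 1L]) / h
  if (n > 2L) d[2:(n - 1L)] <- (r[3:n] - r[1:(n - 2L)]) / (2 * h)
  structure(list(t = t, d_rate = d), class = "rate_derivative")
}

#' @export
print.rate_derivative <- function(x, ...) {
  cat(sprintf("<rate_derivative> %d points, max %.1f Hz/s\n",
              length(x$t), max(x$d_rate)))
  invisible(x)
}

#' Total peak number of firing-rate fluctuation
#'
#' The burst-counting metric: local maxima of the time derivative of the
#' Gaussian-kernel spike density (sigma = 25 ms) are located within the
#' stimulation window, a threshold is set at `threshold_frac` (default 0.5)
#' of the primal peak — the first such maximum, i.e. the rise of the
#' response onset — and the peaks above the threshold are counted. Each
#' accepted peak marks the rising edge of one burst, so a train of k
#' well-separated, comparably sized bursts scores k.
#'
#' Because the Gaussian kernel is acausal, the maximum slope of a burst's
#' density sits up to about one kernel s.d. before the burst's first
#' spike; for a response beginning right at stimulus onset the onset peak
#' would fall just outside the window. The peak search therefore extends
#' `edge_pad` ms (default: one sigma) before the window's left edge.
#'
#' `primal = "max"` instead references the threshold to the largest
#' maximum in the window; the two conventions agree whenever the onset
#' burst is the strongest, as is typical of step-heating responses.
#'
#' @param train a [spike_train()].
#' @param window stimulation window `c(start, end)` (s); defaults to the
#'   train's protocol window.
#' @param sigma kernel s.d. (ms).
#' @param grid_step derivative grid step (ms).
#' @param threshold_frac threshold as a fraction of the primal peak.
#' @param primal reference peak for the threshold: `"first"` (default) or
#'   `"max"`.
#' @param edge_pad extension of the peak search before the window's left
#'   edge (ms).
#' @return an object of class `derivative_peaks`: a list with the
#'   derivative curve (`t`, `d_rate`), accepted `peaks` (times, s),
#'   `peak_values` (Hz/s), `threshold` (Hz/s), `window`, and
#'   `total_peak_number`.
#' @export
total_peak_number <- function(train, window = NULL, sigma = 25,
                              grid_step = 0.1, threshold_frac = 0.5,
                              primal = c("first", "max"),
                              edge_pad = sigma) {
  stopifnot(inherits(train, "spike_train"))
  primal <- match.arg(primal)
  if (is.null(window)) {
    if (is.null(train$protocol)) stop("`window` required (no protocol)")
    window <- stim_window(train$protocol)
  }
  pad <- 5 * sigma / 1000
  dens <- spike_density(train, sigma = sigma,
                        t_range = c(window[1] - pad, window[2] + pad),
                        grid_step = grid_step)
  dv <- rate_derivative(dens, dt_grid = NULL)
  d <- dv$d_rate
  n <- length(d)
  is_max <- c(FALSE, d[2:(n - 1L)] > d[1:(n - 2L)] & d[2:(n - 1L)] >= d[3:n],
              FALSE)
  in_win <- dv$t >= window[1] - edge_pad / 1000 & dv$t <= window[2]
  cand <- which(is_max & in_win & d > 0)
  # collapse plateaus of equal consecutive maxima to their first sample
  if (length(cand) > 1L)
    cand <- cand[c(TRUE, diff(cand) > 1L | diff(d[cand]) != 0)]
  if (!length(cand)) {
    res <- list(t = dv$t, d_rate = d, peaks = numeric(0),
                peak_values = numeric(0), threshold = NA_real_,
                window = window, total_peak_number = 0L)
    return(structure(res, class = "derivative_peaks"))
  }
  primal_value <- if (primal == "max") max(d[cand]) else d[cand[1]]
  thr <- threshold_frac * primal_value
  acc <- cand[d[cand] > thr]
  structure(list(t = dv$t, d_rate = d, peaks = dv$t[acc],
                 peak_values = d[acc], threshold = thr, window = window,
                 total_peak_number = length(acc)),
            class = "derivative_peaks")
}

#' @export
print.derivative_peaks <- function(x, ...) {
  cat(sprintf("<derivative_peaks> %d peak(s) above %.1f Hz/s in [%.2f, %.2f] s\n",
              x$total_peak_number, x$threshold, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
plot.derivative_peaks <- function(x, y, ...) {
  plot(x$t, x$d_rate, type = "l", xlab = "time (s)",
       ylab = "d(rate)/dt (Hz/s)", ...)
  graphics::abline(h = x$threshold, lty = 2, col = "grey40")
  graphics::abline(v = x$window, lty = 3, col = "grey60")
  if (length(x$peaks))
    graphics::points(x$peaks, x$peak_values, col = "red", pch = 1, cex = 1.3)
  invisible(x)
}

#' Stimulus-locked firing-frequency change
#'
#' Average firing frequency during the first `stim_window` seconds of the
#' stimulus minus the average over the `pre_window` seconds preceding it.
#'
#' @param train a [spike_train()].
#' @param stim_onset stimulus onset (s); defaults to the train's protocol.
#' @param pre_window length of the pre-stimulus window (s).
#' @param stim_window length of the stimulus window (s).
#' @return frequency change (Hz).
#' @export
frequency_change <- function(train, stim_onset = NULL, pre_window = 5,
                             stim_window = 5) {
  stopifnot(inherits(train, "spike_train"))
  if (is.null(stim_onset)) {
    if (is.null(train$protocol)) stop("`stim_onset` required (no protocol)")
    stim_onset <- train$protocol$onset
  }
  if (stim_onset - pre_window < train$t_start - 1e-9 ||
      stim_onset + stim_window > train$t_end + 1e-9)
    stop("analysis windows exceed the recording extent")
  pre <- count_in_window(train$times, stim_onset - pre_window, stim_onset)
  dur <- count_in_window(train$times, stim_onset, stim_onset + stim_window)
  dur / stim_window - pre / pre_window
}
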