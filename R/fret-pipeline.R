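#' Co-registered CFP/YFP image stack pair
#'
#' @param cfp,yfp intensity arrays (nx x ny x frames), non-negative, same
#'   shape.
#' @param frame_times frame timestamps (s), one per frame.
#' @param protocol optional [stimulus_protocol()].
#' @param truth optional ground-truth list (synthetic stacks only).
#' @return an object of class `image_stack_pair`.
#' @export
image_stack_pair <- function(cfp, yfp, frame_times, protocol = NULL,
                             truth = NULL) {
  if (!identical(dim(cfp), dim(yfp)))
    stop("CFP and YFP stacks must have identical shapes")
  if (length(dim(cfp)) != 3L) stop("stacks must be nx x ny x frames arrays")
  if (dim(cfp)[3] != length(frame_times))
    stop("`frame_times` must have one entry per frame")
  if (min(cfp) < 0 || min(yfp) < 0) stop("intensities must be non-negative")
  structure(list(cfp = cfp, yfp = yfp, frame_times = as.numeric(frame_times),
                 protocol = protocol, truth = truth),
            class = "image_stack_pair")
}

#' @export
print.image_stack_pair <- function(x, ...) {
  d <- dim(x$cfp)
  cat(sprintf("<image_stack_pair> %d x %d px, %d frames (%.2f - %.2f s)\n",
              d[1], d[2], d[3], x$frame_times[1],
              x$frame_times[length(x$frame_times)]))
  invisible(x)
}

#' Build a binary mask of the dendritic arbor from a FRET stack pair
#'
#' The segmentation pipeline: the CFP and YFP series are multiplied
#' pixel-wise frame by frame, the product series is projected onto the time
#' axis, the projection background is equalized by subtracting a
#' morphological opening with a large structuring element (a rolling-ball
#' style background estimate), connected components are weighted by size so
#' that small speckle is suppressed, and the result is binarized by Otsu's
#' threshold.
#'
#' @param pair an [image_stack_pair()].
#' @param equalize_radius radius (px) of the background-equalization
#'   structuring element; should exceed the dendrite width.
#' @param min_area connected components smaller than this (px) are removed.
#' @return an object of class `binary_mask`: list with logical matrix
#'   `mask` and `provenance` (the parameters used).
#' @export
build_mask <- function(pair, equalize_radius = 9, min_area = 5) {
  stopifnot(inherits(pair, "image_stack_pair"))
  if (dim(pair$cfp)[3] < 2L) stop("need at least 2 frames")
  prod_stack <- pair$cfp * pair$yfp
  proj <- apply(prod_stack, c(1, 2), mean)
  if (max(proj) <= 0) stop("all-zero stacks: cannot build a mask")
  proj <- proj / max(proj)
  brush <- EBImage::makeBrush(2L * equalize_radius + 1L, shape = "disc")
  bg <- EBImage::imageData(EBImage::opening(EBImage::Image(proj), brush))
  eq <- proj - bg
  eq[eq < 0] <- 0
  if (max(eq) <= 0 || stats::sd(eq) < 1e-10)
    stop("no separable foreground after background equalization")
  thr <- EBImage::otsu(EBImage::Image(eq / max(eq)))
  bin <- eq / max(eq) > thr
  lab <- EBImage::bwlabel(EBImage::Image(bin))
  sizes <- table(as.integer(lab)[as.integer(lab) > 0])
  keep <- as.integer(names(sizes)[sizes >= min_area])
  mask <- matrix(as.integer(lab) %in% keep, nrow(bin), ncol(bin))
  structure(list(mask = mask,
                 provenance = list(equalize_radius = equalize_radius,
                                   min_area = min_area, otsu = thr)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground pixels\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' FRET ratio-change trace of one ROI
#'
#' @param t frame times (s).
#' @param dR percent change of the YFP/CFP ratio relative to the
#'   pre-stimulus baseline.
#' @param roi_id ROI label.
#' @param stim_end stimulus cessation time (s).
#' @param stim_onset stimulus onset time (s), if known.
#' @return an object of class `ratio_trace`.
#' @export
ratio_trace <- function(t, dR, roi_id = "roi1", stim_end = NA_real_,
                        stim_onset = NA_real_) {
  stopifnot(length(t) == length(dR))
  structure(list(t = as.numeric(t), dR = as.numeric(dR), roi_id = roi_id,
                 stim_end = stim_end, stim_onset = stim_onset),
            class = "ratio_trace")
}

#' @export
print.ratio_trace <- function(x, ...) {
  cat(sprintf("<ratio_trace> %s: %d frames, range [%.1f, %.1f]%%\n",
              x$roi_id, length(x$t), min(x$dR, na.rm = TRUE),
              max(x$dR, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.ratio_trace <- function(x, y, ...) {
  plot(x$t, x$dR, type = "l", xlab = "time (s)",
       ylab = expression(paste(Delta, "R/R"[0], " (%)")), ...)
  if (is.finite(x$stim_end)) graphics::abline(v = x$stim_end, lty = 3)
  invisible(x)
}

#' Extract a background-subtracted FRET ratio trace from an ROI
#'
#' Within the rectangular ROI, the binary mask separates signal pixels
#' (ROI intersected with the mask) from background pixels (the remainder of
#' the ROI). Per frame, the mean background of each channel is subtracted
#' from its mean signal, the ratio R = (YFP - YFP_bg)/(CFP - CFP_bg) is
#' formed, and the trace is expressed as a percent change relative to the
#' pre-stimulus baseline ratio R0.
#'
#' @param pair an [image_stack_pair()].
#' @param roi integer vector `c(x_min, x_max, y_min, y_max)` (1-based,
#'   inclusive pixel coordinates).
#' @param mask a [build_mask()] result or a logical matrix.
#' @param stim_onset,stim_end stimulus window (s); default from the pair's
#'   protocol.
#' @param baseline length of the pre-stimulus baseline used for R0 (s).
#' @param roi_id ROI label.
#' @return a [ratio_trace()]. Frames where the background-subtracted CFP
#'   signal is non-positive get `NA` and are listed in
#'   `attr(, "flagged_frames")`.
#' @export
extract_ratio_trace <- function(pair, roi, mask, stim_onset = NULL,
                                stim_end = NULL, baseline = 1,
                                roi_id = "roi1") {
  stopifnot(inherits(pair, "image_stack_pair"))
  if (inherits(mask, "binary_mask")) mask <- mask$mask
  d <- dim(pair$cfp)
  if (!identical(dim(mask), d[1:2]))
    stop("mask shape does not match the stacks")
  if (length(roi) != 4L || roi[1] < 1 || roi[3] < 1 ||
      roi[2] > d[1] || roi[4] > d[2] || roi[1] > roi[2] || roi[3] > roi[4])
    stop("invalid ROI rectangle")
  if (is.null(stim_onset) || is.null(stim_end)) {
    if (is.null(pair$protocol))
      stop("stimulus window required (pair has no protocol)")
    w <- stim_window(pair$protocol)
    if (is.null(stim_onset)) stim_onset <- w[1]
    if (is.null(stim_end)) stim_end <- w[2]
  }
  in_roi <- matrix(FALSE, d[1], d[2])
  in_roi[roi[1]:roi[2], roi[3]:roi[4]] <- TRUE
  sig <- in_roi & mask
  bg <- in_roi & !mask
  if (!any(sig)) stop("ROI does not overlap the mask")
  if (!any(bg)) {
    warning("ROI has no background pixels; skipping background subtraction")
  }
  nf <- d[3]
  R <- numeric(nf)
  flagged <- integer(0)
  for (f in seq_len(nf)) {
    cf <- pair$cfp[, , f]; yf <- pair$yfp[, , f]
    c_bg <- if (any(bg)) mean(cf[bg]) else 0
    y_bg <- if (any(bg)) mean(yf[bg]) else 0
    c_sig <- mean(cf[sig]) - c_bg
    y_sig <- mean(yf[sig]) - y_bg
    if (c_sig <= 0) {
      R[f] <- NA_real_
      flagged <- c(flagged, f)
    } else R[f] <- y_sig / c_sig
  }
  base_idx <- pair$frame_times >= stim_onset - baseline &
    pair$frame_times < stim_onset
  if (!any(base_idx)) stop("no frames in the pre-stimulus baseline window")
  R0 <- mean(R[base_idx], na.rm = TRUE)
  out <- ratio_trace(pair$frame_times, 100 * (R - R0) / R0, roi_id = roi_id,
                     stim_end = stim_end, stim_onset = stim_onset)
  attr(out, "flagged_frames") <- flagged
  out
}

#' Peak ratio change of a trial
#'
#' The representative ratio change of a trial: the mean percent ratio
#' change over a fixed window after stimulus cessation (default 400-700 ms
#' after it).
#'
#' @param trace a [ratio_trace()] whose `stim_end` is set.
#' @param window offsets of the averaging window relative to stimulus
#'   cessation (s).
#' @return peak ratio change (%).
#' @export
dr_peak <- function(trace, window = c(0.4, 0.7)) {
  stopifnot(inherits(trace, "ratio_trace"))
  if (!is.finite(trace$stim_end))
    stop("`stim_end` of the trace is unknown")
  if (max(trace$t) < trace$stim_end + window[2] - 1e-9)
    stop("trace does not cover the averaging window")
  idx <- trace$t >= trace$stim_end + window[1] &
    trace$t <= trace$stim_end + window[2]
  if (!any(idx)) stop("no frames in the averaging window")
  mean(trace$dR[idx], na.rm = TRUE)
}

#' Classify a trial as containing a calcium transient
#'
#' A trial is designated a Ca2+ transient when its peak ratio change is
#' strictly larger than the threshold (default 10%).
#'
#' @param dr_peak_value peak ratio change (%), possibly a vector.
#' @param threshold classification threshold (%).
#' @return logical.
#' @export
classify_transient <- function(dr_peak_value, threshold = 10) {
  dr_peak_value > threshold
}

#' Occurrence rate with an exact binomial confidence interval
#'
#' Proportion of positive trials with its Clopper-Pearson (exact binomial)
#' 95% confidence interval, the summary used for transient occurrence and
#' behavioural response rates.
#'
#' @param classifications logical vector (one entry per trial).
#' @param conf_level confidence level.
#' @return a list with `proportion` (%), `ci_lower`, `ci_upper` (%),
#'   `n_positive` and `n`.
#' @export
occurrence_rate <- function(classifications, conf_level = 0.95) {
  if (!length(classifications)) stop("need at least one trial")
  k <- sum(classifications)
  n <- length(classifications)
  ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
  list(proportion = 100 * k / n, ci_lower = 100 * ci[1],
       ci_upper = 100 * ci[2], n_positive = k, n = n)
}

#' Estimate a photobleaching baseline from a fluorescence trace
#'
#' Fits a monoexponential decay with offset, I(t) = c + a exp(-k t), to the
#' frames that lie outside the irradiation windows, so that
#' stimulus-evoked dips do not bias the bleaching estimate. Residuals from
#' the fitted curve quantify transient attenuation and recovery.
#'
#' @param values fluorescence intensities, one per frame.
#' @param times frame times (s).
#' @param irradiation_windows two-column matrix of window start/end times
#'   (s); frames inside any window are excluded from the fit.
#' @return a list with `fitted` (curve over all frames), `coef`
#'   (`c`, `a`, `k`), `residuals`, `converged`, and `excluded` (logical,
#'   frames left out of the fit). If the nonlinear fit fails to converge
#'   the result is flagged (`converged = FALSE`) and a linear trend is
#'   returned instead.
#' @export
bleach_baseline <- function(values, times,
                            irradiation_windows = matrix(numeric(0), 0, 2)) {
  stopifnot(length(values) == length(times))
  excl <- rep(FALSE, length(times))
  if (nrow(irradiation_windows))
    for (i in seq_len(nrow(irradiation_windows)))
      excl <- excl | (times >= irradiation_windows[i, 1] &
                        times <= irradiation_windows[i, 2])
  if (sum(!excl) < 3L) stop("need at least 3 frames outside irradiation")
  tf <- times[!excl]; vf <- values[!excl]
  if (stats::sd(vf) < 1e-12) {
    fitted <- rep(mean(vf), length(times))
    return(list(fitted = fitted, coef = c(c = mean(vf), a = 0, k = 0),
                residuals = values - fitted, converged = TRUE,
                excluded = excl))
  }
  c0 <- min(vf) - 0.05 * abs(min(vf))
  pos <- vf - c0 > 0
  k0 <- tryCatch({
    f <- stats::lm(log(vf[pos] - c0) ~ tf[pos])
    max(1e-6, -stats::coef(f)[2])
  }, error = function(e) 0.1)
  fit <- tryCatch(
    minpack.lm::nlsLM(vf ~ c + a * exp(-k * tf),
                      start = list(c = c0, a = max(vf) - c0, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    lf <- stats::lm(vf ~ tf)
    fitted <- as.numeric(stats::predict(lf, data.frame(tf = times)))
    warning("bleach fit did not converge; returning linear trend")
    return(list(fitted = fitted,
                coef = c(c = unname(stats::coef(lf)[1]),
                         a = unname(stats::coef(lf)[2]), k = NA_real_),
                residuals = values - fitted, converged = FALSE,
                excluded = excl))
  }
  cf <- stats::coef(fit)
  fitted <- cf["c"] + cf["a"] * exp(-cf["k"] * times)
  list(fitted = fitted, coef = cf, residuals = values - fitted,
       converged = TRUE, excluded = excl)
}
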