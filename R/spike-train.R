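#' Spike train for one trial
#'
#' A sorted sequence of spike times for one recording trial, together with
#' the stimulus protocol and the extent of the recording. All firing metrics
#' operate on this container; interspike intervals (ISIs) are differences of
#' consecutive times.
#'
#' @param times spike times (s), strictly increasing.
#' @param protocol a [stimulus_protocol()] or `NULL`.
#' @param trial_id trial label.
#' @param t_start,t_end extent of the recording (s). Defaults to 0 and the
#'   later of the last spike and the end of the stimulus.
#'
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, protocol = NULL, trial_id = "trial1",
                        t_start = 0, t_end = NULL) {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times)))
    stop("spike times must be finite")
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (!is.null(protocol) && !inherits(protocol, "stimulus_protocol"))
    stop("`protocol` must be a stimulus_protocol or NULL")
  if (is.null(t_end)) {
    t_end <- max(t_start,
                 if (length(times)) max(times) else t_start,
                 if (!is.null(protocol)) stim_window(protocol)[2] else t_start)
  }
  if (length(times) && (times[1] < t_start || times[length(times)] > t_end))
    stop("spike times outside the recording extent")
  structure(list(times = times, protocol = protocol, trial_id = trial_id,
                 t_start = t_start, t_end = t_end),
            class = "spike_train")
}

#' Interspike intervals
#'
#' @param train a [spike_train()].
#' @return ISIs in milliseconds (length `n_spikes - 1`).
#' @export
isi <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  diff(train$times) * 1000
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes over [%.3f, %.3f] s\n",
              x$trial_id, length(x$times), x$t_start, x$t_end))
  if (!is.null(x$protocol))
    cat(sprintf("  stimulus: %s at %.3f s for %.3f s\n", x$protocol$kind,
                x$protocol$onset, x$protocol$duration))
  invisible(x)
}

#' @export
plot.spike_train <- function(x, y, ..., main = x$trial_id) {
  plot(NA, xlim = c(x$t_start, x$t_end), ylim = c(0, 1), yaxt = "n",
       xlab = "time (s)", ylab = "", main = main, ...)
  if (!is.null(x$protocol)) {
    on <- stim_on_intervals(x$protocol)
    graphics::rect(on[, 1], 0, on[, 2], 1, col = "#ffddcc", border = NA)
  }
  if (length(x$times))
    graphics::segments(x$times, 0.2, x$times, 0.8)
  invisible(x)
}

# number of spikes strictly before time t (vectorised over t)
n_spikes_before <- function(times, t) findInterval(t, times, left.open = TRUE)

# spike count in the half-open window [t0, t1)
count_in_window <- function(times, t0, t1)
  n_spikes_before(times, t1) - n_spikes_before(times, t0)
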