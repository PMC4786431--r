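#' Stimulus protocol description
#'
#' Describes a single stimulation epoch: a step-like IR-laser heat pulse, a
#' continuous blue-light exposure, or a pulsed (intermittent) light protocol
#' such as 5 cycles of 100 ms pulses separated by 100 ms pauses. Onset and
#' duration are recorded on the same clock as spike times and frame
#' timestamps.
#'
#' @param kind one of `"IR"`, `"light_continuous"`, `"light_pulsed"`.
#' @param onset stimulus onset (s).
#' @param duration total stimulus duration (s); for pulsed protocols this is
#'   the span from the first pulse onset to the end of the last cycle.
#' @param power nominal power (mW for IR, mW/mm^2 for light).
#' @param pulse_on,pulse_off on/off phase durations (ms), pulsed only.
#' @param n_pulses number of on-phases, pulsed only.
#'
#' @return an object of class `stimulus_protocol`.
#' @examples
#' ir_protocol()
#' pulsed_light_protocol()
#' @export
stimulus_protocol <- function(kind = c("IR", "light_continuous", "light_pulsed"),
                              onset, duration, power = NA_real_,
                              pulse_on = NULL, pulse_off = NULL,
                              n_pulses = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(onset), length(onset) == 1L, is.finite(onset))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be a single positive number (seconds)")
  if (kind == "light_pulsed") {
    if (is.null(pulse_on) || is.null(pulse_off) || is.null(n_pulses))
      stop("pulsed protocols require `pulse_on`, `pulse_off` and `n_pulses`")
    if (pulse_on <= 0 || pulse_off < 0 || n_pulses < 1)
      stop("invalid pulse parameters")
    # the trailing pause may extend past `duration`
    if (n_pulses * (pulse_on + pulse_off) > duration * 1000 + pulse_off + 1e-9)
      stop("pulse cycles do not fit within `duration`")
  } else {
    pulse_on <- pulse_off <- n_pulses <- NULL
  }
  structure(list(kind = kind, onset = onset, duration = duration,
                 power = power, pulse_on = pulse_on, pulse_off = pulse_off,
                 n_pulses = n_pulses),
            class = "stimulus_protocol")
}

#' @rdname stimulus_protocol
#' @export
ir_protocol <- function(onset = 1, duration = 1, power = 30)
  stimulus_protocol("IR", onset = onset, duration = duration, power = power)

#' @rdname stimulus_protocol
#' @param ... passed on to `stimulus_protocol()`.
#' @export
pulsed_light_protocol <- function(onset = 1, n_pulses = 5, pulse_on = 100,
                                  pulse_off = 100, power = 0.294, ...) {
  duration <- (n_pulses * (pulse_on + pulse_off) - pulse_off) / 1000
  stimulus_protocol("light_pulsed", onset = onset, duration = duration,
                    power = power, pulse_on = pulse_on,
                    pulse_off = pulse_off, n_pulses = n_pulses, ...)
}

#' Stimulation window and on-phase intervals of a protocol
#'
#' `stim_window()` returns the overall `[onset, onset + duration]` interval.
#' `stim_on_intervals()` returns the intervals during which the stimulus is
#' actually delivered: the whole window for IR and continuous light, the
#' individual on-phases for pulsed light.
#'
#' @param protocol a [stimulus_protocol()].
#' @return `stim_window()`: numeric length-2 vector (s). `stim_on_intervals()`:
#'   two-column matrix of interval start/end times (s), one row per phase.
#' @export
stim_window <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  c(protocol$onset, protocol$onset + protocol$duration)
}

#' @rdname stim_window
#' @export
stim_on_intervals <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (protocol$kind != "light_pulsed") {
    m <- matrix(stim_window(protocol), ncol = 2)
  } else {
    cyc <- (protocol$pulse_on + protocol$pulse_off) / 1000
    starts <- protocol$onset + (seq_len(protocol$n_pulses) - 1L) * cyc
    m <- cbind(starts, starts + protocol$pulse_on / 1000)
  }
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol>", x$kind, "\n")
  cat(sprintf("  onset %.3f s, duration %.3f s, power %s\n",
              x$onset, x$duration,
              if (is.na(x$power)) "NA" else format(x$power)))
  if (x$kind == "light_pulsed")
    cat(sprintf("  %d pulses of %g ms on / %g ms off\n",
                x$n_pulses, x$pulse_on, x$pulse_off))
  invisible(x)
}
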