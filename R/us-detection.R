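#' Unconventional-spike (US) definition
#'
#' A US is extracted from three sequential spikes when (1) the first
#' interspike interval is shorter than `isi1_max` and (2) the second is
#' longer than `isi2_min`; the first and second spikes of the triplet form
#' the US pair. The standard bounds are 9 and 20 ms; the blue-light
#' redefinition relaxes the first bound to 15 ms.
#'
#' @param isi1_max exclusive upper bound on the first ISI (ms).
#' @param isi2_min exclusive lower bound on the second ISI (ms).
#' @return an object of class `us_definition`.
#' @export
us_definition <- function(isi1_max = 9, isi2_min = 20) {
  if (isi1_max <= 0 || isi2_min <= 0)
    stop("ISI bounds must be positive (ms)")
  structure(list(isi1_max = isi1_max, isi2_min = isi2_min),
            class = "us_definition")
}

#' @export
print.us_definition <- function(x, ...) {
  cat(sprintf("<us_definition> ISI1 < %g ms and ISI2 > %g ms\n",
              x$isi1_max, x$isi2_min))
  invisible(x)
}

#' Detect unconventional spikes in a train
#'
#' Scans consecutive spike triplets left to right and emits a US pair
#' whenever the triplet satisfies the definition. Under the default greedy
#' rule a spike consumed by a US pair is not reused as the first element of
#' the following triplet (the triplet's third spike may start the next
#' one); `mode = "all"` scans every triplet without consumption, for
#' sensitivity analysis.
#'
#' @param train a [spike_train()].
#' @param definition a [us_definition()].
#' @param window analysis window `c(start, end)` in seconds; defaults to
#'   the train's stimulation window, `NULL` protocol means the whole
#'   recording. Both spikes of an emitted pair must lie in the window (the
#'   triplet's third spike may fall outside it).
#' @param mode `"greedy"` (default) or `"all"`.
#' @return a data frame of class `us_events` with columns `first_spike`,
#'   `second_spike` (s), `isi1_ms`, `isi2_ms` and `trial_id`; zero rows when
#'   the train has fewer than three spikes or no triplet qualifies.
#' @export
detect_us <- function(train, definition = us_definition(), window = NULL,
                      mode = c("greedy", "all")) {
  stopifnot(inherits(train, "spike_train"),
            inherits(definition, "us_definition"))
  mode <- match.arg(mode)
  if (is.null(window))
    window <- if (!is.null(train$protocol)) stim_window(train$protocol)
              else c(train$t_start, train$t_end)
  tt <- train$times
  n <- length(tt)
  empty <- data.frame(first_spike = numeric(0), second_spike = numeric(0),
                      isi1_ms = numeric(0), isi2_ms = numeric(0),
                      trial_id = character(0))
  if (n < 3L) return(structure(empty, class = c("us_events", "data.frame")))
  first <- second <- i1 <- i2 <- numeric(0)
  i <- 1L
  while (i <= n - 2L) {
    isi1 <- (tt[i + 1L] - tt[i]) * 1000
    isi2 <- (tt[i + 2L] - tt[i + 1L]) * 1000
    hit <- isi1 < definition$isi1_max && isi2 > definition$isi2_min &&
      tt[i] >= window[1] && tt[i + 1L] <= window[2]
    if (hit) {
      first <- c(first, tt[i]); second <- c(second, tt[i + 1L])
      i1 <- c(i1, isi1); i2 <- c(i2, isi2)
    }
    i <- i + if (hit && mode == "greedy") 2L else 1L
  }
  structure(data.frame(first_spike = first, second_spike = second,
                       isi1_ms = i1, isi2_ms = i2,
                       trial_id = rep(train$trial_id, length(first))),
            class = c("us_events", "data.frame"))
}

#' Compare the minimum ISI within USs to the minimum among non-US pairs
#'
#' For one trial, returns the minimum first-ISI over the detected US pairs
#' and the minimum ISI over all consecutive spike pairs that were not
#' designated as a US pair.
#'
#' @param train a [spike_train()].
#' @param us_events the result of [detect_us()] on the same train.
#' @return a list with `us_min_ms` (NA with a warning when the trial has no
#'   US) and `non_us_min_ms` (NA when every pair is a US pair).
#' @export
min_isi_comparison <- function(train, us_events) {
  stopifnot(inherits(train, "spike_train"), inherits(us_events, "data.frame"))
  all_isi <- isi(train)
  if (!length(all_isi))
    return(list(us_min_ms = NA_real_, non_us_min_ms = NA_real_))
  firsts <- train$times[-length(train$times)]
  is_us_pair <- firsts %in% us_events$first_spike
  us_min <- if (nrow(us_events)) min(us_events$isi1_ms) else {
    warning("trial has no US; within-US minimum is undefined")
    NA_real_
  }
  non_us_min <- if (any(!is_us_pair)) min(all_isi[!is_us_pair]) else NA_real_
  list(us_min_ms = us_min, non_us_min_ms = non_us_min)
}

#' Sweep US definitions and correlate US counts with calcium responses
#'
#' For every US definition on a grid, counts USs per trial and computes the
#' Spearman rank correlation between the per-trial US count and the
#' per-trial peak FRET-ratio change.
#'
#' @param trials a list; each element has `$train` (a [spike_train()]) and
#'   `$dr_peak` (numeric).
#' @param grid a data frame with columns `isi1_max` and `isi2_min` (ms), or
#'   a list of [us_definition()] objects.
#' @param window passed to [detect_us()].
#' @return a data frame with one row per definition: `isi1_max`,
#'   `isi2_min`, `rho`, `p` and `degenerate` (TRUE when the US counts were
#'   constant across trials and the correlation is undefined).
#' @export
us_parameter_sweep <- function(trials, grid, window = NULL) {
  if (length(trials) < 5L) stop("need at least 5 trials")
  if (is.data.frame(grid)) {
    defs <- Map(us_definition, grid$isi1_max, grid$isi2_min)
  } else defs <- grid
  dr <- vapply(trials, function(tr) tr$dr_peak, numeric(1))
  out <- data.frame(isi1_max = numeric(0), isi2_min = numeric(0),
                    rho = numeric(0), p = numeric(0), degenerate = logical(0))
  for (d in defs) {
    cnt <- vapply(trials, function(tr)
      nrow(detect_us(tr$train, d, window = window)), numeric(1))
    if (length(unique(cnt)) == 1L) {
      out <- rbind(out, data.frame(isi1_max = d$isi1_max,
                                   isi2_min = d$isi2_min, rho = NA_real_,
                                   p = NA_real_, degenerate = TRUE))
    } else {
      sc <- spearman_cor(cnt, dr)
      out <- rbind(out, data.frame(isi1_max = d$isi1_max,
                                   isi2_min = d$isi2_min, rho = sc$rho,
                                   p = sc$p, degenerate = FALSE))
    }
  }
  out
}
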