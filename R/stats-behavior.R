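#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value is exact for
#' small tie-free samples and asymptotic otherwise (the behaviour of
#' [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a list with `rho`, `p` and `degenerate` (TRUE, with `rho = NA`,
#'   when either vector is constant).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Wilcoxon rank tests
#'
#' Rank-sum (Mann-Whitney) test for independent samples or signed-rank
#' test for paired samples; zero paired differences are excluded per the
#' standard convention.
#'
#' @param x,y numeric samples.
#' @param paired use the signed-rank test.
#' @return p-value; all-tied data yield `NA` with a warning.
#' @export
wilcoxon_p <- function(x, y, paired = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per group")
  if (paired && length(x) != length(y))
    stop("paired samples must have equal length")
  if (paired && all(x == y)) {
    warning("all paired differences are zero")
    return(NA_real_)
  }
  if (!paired && stats::sd(c(x, y)) == 0) {
    warning("all observations tied")
    return(NA_real_)
  }
  suppressWarnings(stats::wilcox.test(x, y, paired = paired)$p.value)
}

#' Two-tailed Fisher's exact test
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-tailed p-value.
#' @export
fisher_exact_p <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("empty margin")
  stats::fisher.test(table)$p.value
}

#' Bonferroni correction
#'
#' @param p p-values.
#' @param m number of comparisons, at least `length(p)`.
#' @return adjusted p-values `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < length(p)) stop("`m` must be at least the number of tests")
  pmin(1, m * p)
}

#' Maximum stride speed before and after an activation event
#'
#' Frame-to-frame crawling speed (displacement over frame interval) of a
#' tracked larva, with the maxima over fixed windows before and after the
#' optogenetic activation onset.
#'
#' @param track data frame with columns `t` (s) and `x`, `y` (mm), sampled
#'   at the video frame rate.
#' @param event_time activation onset (s).
#' @param window window length on each side of the event (s).
#' @param smooth optional centred moving-average span (frames, odd) applied
#'   to the speed series; 1 disables smoothing.
#' @return a list with `pre_max` and `post_max` (mm/s).
#' @export
max_stride_speed <- function(track, event_time, window = 5, smooth = 1) {
  stopifnot(is.data.frame(track), all(c("t", "x", "y") %in% names(track)))
  if (is.unsorted(track$t, strictly = TRUE)) stop("track times must increase")
  if (min(track$t) > event_time - window + 1e-9 ||
      max(track$t) < event_time + window - 1e-9)
    stop("track does not cover the analysis windows")
  v <- sqrt(diff(track$x)^2 + diff(track$y)^2) / diff(track$t)
  tm <- (track$t[-1] + track$t[-nrow(track)]) / 2
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    v <- as.numeric(stats::filter(v, k, sides = 2))
  }
  pre <- v[tm >= event_time - window & tm < event_time]
  post <- v[tm >= event_time & tm < event_time + window]
  list(pre_max = max(pre, na.rm = TRUE), post_max = max(post, na.rm = TRUE))
}
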