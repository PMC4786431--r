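# Independent reference implementations used to cross-check the package.

# Maximum window count by exhaustive pair enumeration: any placement of a
# half-open window of length `dt_s` holding spikes i..j requires
# t_j - t_i < dt_s; the maximum count is the largest such j - i + 1.
oracle_max_window_count <- function(times, dt_s) {
  n <- length(times)
  if (n == 0L) return(0L)
  best <- 1L
  for (i in seq_len(n)) {
    j <- i
    while (j < n && times[j + 1L] - times[i] < dt_s) j <- j + 1L
    best <- max(best, j - i + 1L)
  }
  best
}

# US extraction by explicit scan over the ISI sequence, applying the
# left-to-right consumption rule on indices rather than on triplets.
oracle_us_first_spikes <- function(times, isi1_max, isi2_min, window,
                                   greedy = TRUE) {
  n <- length(times)
  if (n < 3L) return(numeric(0))
  isis <- diff(times) * 1000
  qualifies <- function(i) {
    isis[i] < isi1_max && isis[i + 1L] > isi2_min &&
      times[i] >= window[1] && times[i + 1L] <= window[2]
  }
  out <- numeric(0)
  i <- 1L
  while (i <= n - 2L) {
    if (qualifies(i)) {
      out <- c(out, times[i])
      i <- i + (if (greedy) 2L else 1L)
    } else i <- i + 1L
  }
  out
}

# Clopper-Pearson interval from beta quantiles.
oracle_clopper_pearson <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- ifelse(k == 0, 0, qbeta(a, k, n - k + 1))
  hi <- ifelse(k == n, 1, qbeta(1 - a, k + 1, n - k))
  cbind(lo, hi)
}

# Exact two-sided rank-sum p-value by enumeration of group assignments.
oracle_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  w_all <- apply(combs, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Exact two-sided Fisher p-value by hypergeometric enumeration.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(m, k)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact Spearman permutation p-value (two-sided) for tiny n.
oracle_spearman_p <- function(x, y) {
  rho_obs <- cor(rank(x), rank(y))
  perms <- permutations_of(length(y))
  rhos <- apply(perms, 1L, function(p) cor(rank(x), rank(y[p])))
  mean(abs(rhos) >= abs(rho_obs) - 1e-9)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# Random spike train on [0, t_end] (uniform order statistics), optionally
# clustered to create short ISIs.
random_train <- function(n, t_end = 3, seed = 1, protocol = NULL,
                         cluster = FALSE) {
  set.seed(seed)
  tt <- sort(runif(n, 0, t_end))
  if (cluster && n > 4) {
    k <- sample(seq_len(n - 1L), max(1L, n %/% 5))
    tt[k + 1L] <- tt[k] + runif(length(k), 0.001, 0.012)
    tt <- sort(tt)
    tt <- tt[c(diff(tt) > 1e-6, TRUE)]
  }
  spike_train(unique(tt), protocol = protocol, t_start = 0,
              t_end = max(t_end, max(tt)))
}

# Deterministic pulse-locked train: k bursts of `spikes_per_burst` spikes
# at `burst_rate` Hz, burst onsets `period` s apart starting at `t0`.
locked_burst_train <- function(k, t0 = 1, period = 0.2, spikes_per_burst = 5,
                               burst_rate = 100, protocol = NULL) {
  on <- t0 + (seq_len(k) - 1L) * period
  tt <- as.vector(vapply(on, function(s)
    s + 0.005 + (seq_len(spikes_per_burst) - 1L) / burst_rate,
    numeric(spikes_per_burst)))
  spike_train(sort(tt), protocol = protocol, t_start = 0,
              t_end = max(tt) + 1)
}
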