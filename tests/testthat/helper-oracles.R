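# Independent oracles used across the suite. These deliberately recompute
# quantities by the most direct route available (stats::cor loops, manual
# 2x2 tabulation, dhyper enumeration) so they share no code with the
# implementation they check.

# brute-force leave-one-out correlations via stats::cor
oracle_loo <- function(x, y) {
  vapply(seq_along(x), function(i) {
    r <- suppressWarnings(stats::cor(x[-i], y[-i]))
    if (is.na(r)) -Inf else r
  }, numeric(1))
}

# independent re-implementation of the greedy loop: recompute every
# leave-one-out correlation with stats::cor at every step
oracle_greedy <- function(x, y, min_cohort = 3, tol = 1e-12) {
  idx <- seq_along(x)
  removed <- integer(0)
  repeat {
    if (length(idx) <= min_cohort) break
    r <- stats::cor(x[idx], y[idx])
    r_loo <- vapply(seq_along(idx), function(i) {
      v <- suppressWarnings(stats::cor(x[idx[-i]], y[idx[-i]]))
      if (is.na(v)) -Inf else v
    }, numeric(1))
    if (max(r_loo) - r <= tol) break
    pick <- which.max(r_loo)   # first maximum = lowest-index tie rule
    removed <- c(removed, idx[pick])
    idx <- idx[-pick]
  }
  list(kept = idx, removed = removed)
}

# manual two-group log-rank by explicit 2x2 tabulation at each event time
oracle_logrank <- function(time, event, grp1) {
  te <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in te) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & grp1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (o1 - e1)^2 / v
  list(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# two-sided Fisher exact p by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # in-set size
  k <- a + c          # total hits
  n_tot <- a + b + c + d
  support <- max(0, k - (n_tot - m)):min(m, k)
  probs <- stats::dhyper(support, m, n_tot - m, k)
  p_obs <- stats::dhyper(a, m, n_tot - m, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand-applied Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# small random expression matrix with dimnames
random_matrix <- function(n_probes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_probes * n_samples), n_probes, n_samples,
         dimnames = list(sprintf("P%03d", seq_len(n_probes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
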