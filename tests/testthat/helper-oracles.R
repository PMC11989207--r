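# Independent brute-force oracle for the two-sided 2x2 Fisher test: sums
# hypergeometric point probabilities no larger than the observed one,
# working directly from dhyper rather than from table enumeration.
fisher_2x2_oracle <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  pk <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(pk[pk <= p_obs * (1 + 1e-9)])
}

# all 2x2 tables with grand total <= n_max and strictly positive margins
all_2x2_tables <- function(n_max) {
  out <- list()
  for (a in 0:n_max) for (b in 0:(n_max - a)) {
    for (cc in 0:(n_max - a - b)) for (d in 0:(n_max - a - b - cc)) {
      m <- matrix(c(a, cc, b, d), 2, 2)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
        out[[length(out) + 1L]] <- m
      }
    }
  }
  out
}

# small right-censored samples for survival cross-checks
random_survival_sample <- function(n, censor_frac = 0.3) {
  times <- round(stats::rexp(n, rate = 0.1), 2)
  events <- as.integer(stats::runif(n) > censor_frac)
  list(times = times, events = events)
}
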