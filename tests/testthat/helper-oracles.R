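# Independent brute-force oracles. These deliberately use the slowest,
# most literal formulation of each quantity and share no code with the
# implementation they check.

# Alteration prevalence by expanding the histogram to one entry per read.
oracle_prevalence <- function(counts, ref_len) {
  reads <- rep(as.integer(names(counts)), times = counts)
  if (length(reads) == 0) return(NA_real_)
  altered <- 0
  for (r in reads) {
    if (r <= ref_len - 2 || r > ref_len) altered <- altered + 1
  }
  altered / length(reads)
}

# Barnard p by literal enumeration: for each nuisance value, loop over
# every possible outcome table and accumulate the probability of those at
# least as extreme as observed (pooled score statistic).
oracle_barnard <- function(a, b, c, d, n_grid = 1001) {
  n1 <- a + b; n2 <- c + d
  if (n1 == 0 || n2 == 0) return(1)
  zstat <- function(x1, x2) {
    pp <- (x1 + x2) / (n1 + n2)
    den <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    if (den == 0) 0 else (x1 / n1 - x2 / n2) / den
  }
  z_obs <- zstat(a, c)
  if (abs(z_obs) < 1e-12) return(1)
  p_max <- 0
  for (g in seq_len(n_grid)) {
    pi <- g / (n_grid + 1)
    tot <- 0
    for (x1 in 0:n1) {
      for (x2 in 0:n2) {
        if (abs(zstat(x1, x2)) >= abs(z_obs) - 1e-10) {
          tot <- tot + dbinom(x1, n1, pi) * dbinom(x2, n2, pi)
        }
      }
    }
    if (tot > p_max) p_max <- tot
  }
  min(p_max, 1)
}

# Two-sided Fisher p as the sum of hypergeometric table probabilities at
# most as large as the observed table's.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand product-limit estimator.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    deaths <- sum(time == ts[i] & event)
    s <- s * (1 - deaths / at_risk)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}
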