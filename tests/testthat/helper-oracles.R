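# Independent oracles used by the unit and acceptance tests. These are
# deliberately written against the definitions (basis vectors, double
# loops over splits and thresholds) rather than the package's recursive /
# incremental implementations.

# Haar coefficients by explicit inner products with the scaling / wavelet
# basis vectors: level-i scaling vector j is 2^(-i/2) on the covered block;
# the wavelet vector is +2^(-i/2) on the left half, -2^(-i/2) on the right.
oracle_haar_level <- function(z, level) {
  n <- length(z)
  m <- n / 2^level
  trend <- numeric(m)
  fluct <- numeric(m)
  for (j in seq_len(m)) {
    block <- z[((j - 1) * 2^level + 1):(j * 2^level)]
    half <- length(block) / 2
    trend[j] <- sum(block) * 2^(-level / 2)
    fluct[j] <- (sum(block[1:half]) - sum(block[(half + 1):(2 * half)])) *
      2^(-level / 2)
  }
  list(trend = trend, fluct = fluct)
}

# Brute-force scaled two-sample KS split scan: double loop over splits and
# pooled thresholds.
oracle_ks_scan <- function(z) {
  n <- length(z)
  m_seq <- 2:(n - 2)
  thresholds <- sort(unique(z))
  stat <- vapply(m_seq, function(m) {
    left <- z[1:m]
    right <- z[(m + 1):n]
    d <- max(vapply(thresholds, function(t) {
      abs(mean(left <= t) - mean(right <= t))
    }, numeric(1)))
    sqrt(m * (n - m) / n) * d
  }, numeric(1))
  list(split = m_seq, statistic = stat,
       est_cp = m_seq[which.max(stat)], max = max(stat))
}

# Brute-force global scaled two-sample KS statistic over pooled points.
oracle_ks_global <- function(x, z) {
  pool <- c(x, z)
  sqrt(length(x) * length(z) / (length(x) + length(z))) *
    max(vapply(pool, function(t) abs(mean(z <= t) - mean(x <= t)),
               numeric(1)))
}

# Noiseless step series: k zeros followed by N - k values at v.
step_series <- function(N, k, v = 100) c(rep(0, k), rep(v, N - k))
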