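#' Exhaustive scaled two-sample KS split scan
#'
#' The classical baseline: for every candidate split `m` in `[2, n - 2]`
#' the series is divided into its first `m` and last `n - m` samples and
#' the scaled two-sample KS statistic
#' `sqrt(m (n - m) / n) * sup_t |F_left(t) - F_right(t)|`
#' is computed between the two segments. The estimated change point is the
#' argmax (smallest split on ties). Both segments keep at least two points
#' so the scan range matches the Welch scan.
#'
#' @param diag_z Numeric vector, length at least 4.
#' @param alpha Significance level for the changed verdict (asymptotic
#'   Kolmogorov critical value).
#' @return A `cp_result` carrying the full split profile.
#' @examples
#' detect_ks_scan(c(0, 0, 0, 0, 1, 1, 1, 1))
#' @export
detect_ks_scan <- function(diag_z, alpha = 0.05) {
  z <- check_series(diag_z, min_len = 4L)
  n <- length(z)
  ord <- order(z)
  zs <- z[ord]
  # rank of each original position in the sorted order (ties broken by order)
  rk <- integer(n)
  rk[ord] <- seq_len(n)
  # evaluate F only at the upper end of each tied run of sorted values
  keep <- c(zs[-n] != zs[-1L], TRUE)
  j <- seq_len(n)
  m_seq <- 2:(n - 2L)
  stat <- numeric(length(m_seq))
  cnt <- numeric(n)       # cnt[j] = #(i <= m with rank_i <= j)
  cnt[rk[1L]:n] <- 1
  for (idx in seq_along(m_seq)) {
    m <- m_seq[idx]
    cnt[rk[m]:n] <- cnt[rk[m]:n] + 1
    d <- abs(cnt / m - (j - cnt) / (n - m))
    stat[idx] <- sqrt(m * (n - m) / n) * max(d[keep])
  }
  best <- which.max(stat)
  crit <- ks_critical_value(alpha)
  new_cp_result(
    method = "ks", n = n, est_cp = m_seq[best],
    changed = stat[best] > crit, statistic = stat[best],
    profile = tibble::tibble(split = m_seq, statistic = stat),
    n_stat_evals = length(m_seq),
    config = list(alpha = alpha, critical = crit))
}

#' One-level Haar detail-maximum detector
#'
#' Computes the one-level fluctuation coefficients
#' `cD[j] = (z[2j-1] - z[2j]) / sqrt(2)` and locates the pair with the
#' largest absolute coefficient (`j*`, smallest index on ties); the
#' estimated change point is the left element of that pair,
#' `2 j* - 1`. The changed verdict compares `|cD[j*]|` to a critical value
#' `gamma = sd_est * sqrt(2 * log(n / 2))`, the Gaussian maximal-noise
#' level, with `sd_est` the median-absolute-deviation estimate of the
#' detail-coefficient scale. A step falling on a pair boundary (even
#' change point) leaves every within-pair difference untouched, so this
#' detector is structurally blind there.
#'
#' @param diag_z Numeric vector of even length.
#' @param gamma Optional critical value overriding the MAD-based default.
#' @return A `cp_result` carrying the per-pair coefficient profile.
#' @export
detect_hw_onelevel <- function(diag_z, gamma = NULL) {
  z <- check_series(diag_z)
  n <- length(z)
  if (n %% 2L != 0L) {
    stop("detect_hw_onelevel() needs an even-length series; got ", n,
         call. = FALSE)
  }
  cd <- haar_step(z)$fluct
  j_star <- which.max(abs(cd))
  if (is.null(gamma)) {
    gamma <- stats::mad(cd) * sqrt(2 * log(n / 2))
  }
  new_cp_result(
    method = "hw", n = n, est_cp = 2L * j_star - 1L,
    changed = abs(cd[j_star]) > gamma, statistic = abs(cd[j_star]),
    profile = tibble::tibble(split = 2L * seq_along(cd) - 1L,
                             statistic = abs(cd)),
    n_stat_evals = length(cd),
    config = list(gamma = gamma))
}

#' Welch t split scan
#'
#' For every candidate split `m` in `[2, n - 2]` the Welch t statistic
#' `T(m) = (mean_L - mean_R) / sqrt(s_L^2 / m + s_R^2 / (n - m))`
#' is computed with unbiased segment variances; each variance is floored at
#' 1e-12 so that noiseless steps return a finite, maximal statistic at the
#' true split. The estimated change point is the argmax of `|T|` (smallest
#' split on ties). Used as a locator only; no p-value is attached.
#'
#' @param diag_z Numeric vector, length at least 4.
#' @return A `cp_result` carrying the full `|T|` profile.
#' @export
detect_welch_t <- function(diag_z) {
  z <- check_series(diag_z, min_len = 4L)
  n <- length(z)
  m <- 2:(n - 2L)
  cs <- cumsum(z)
  cs2 <- cumsum(z^2)
  mean_l <- cs[m] / m
  mean_r <- (cs[n] - cs[m]) / (n - m)
  var_l <- pmax((cs2[m] - cs[m]^2 / m) / (m - 1), 1e-12)
  var_r <- pmax(((cs2[n] - cs2[m]) - (cs[n] - cs[m])^2 / (n - m)) /
                  (n - m - 1), 1e-12)
  tstat <- (mean_l - mean_r) / sqrt(var_l / m + var_r / (n - m))
  best <- which.max(abs(tstat))
  new_cp_result(
    method = "t", n = n, est_cp = m[best],
    changed = NA, statistic = abs(tstat[best]),
    profile = tibble::tibble(split = m, statistic = tstat),
    n_stat_evals = length(m),
    config = list())
}
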