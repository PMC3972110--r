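#' Simulation cell configuration
#'
#' One Monte-Carlo design cell: a diagnosed series of power-of-two length
#' `N` whose first `k` samples are N(0, sd^2) and whose remaining `N - k`
#' samples have the constant shift `v` added, replicated `reps` times under
#' a deterministic seeding scheme.
#'
#' @param N Power-of-two series length.
#' @param k Change position, `1 <= k <= N - 1` (size of the normal
#'   segment).
#' @param v Mean shift added after position `k` (signal units).
#' @param sd Noise standard deviation (> 0), default 1.
#' @param seed Base seed of the cell.
#' @param reps Replicate count (>= 1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(N, k, v, sd = 1, seed = 0, reps = 1) {
  N <- as.integer(N)
  k <- as.integer(k)
  if (N < 2L || bitwAnd(N, N - 1L) != 0L) {
    stop("N must be a power of two >= 2; got ", N, call. = FALSE)
  }
  if (k < 1L || k > N - 1L) {
    stop("k must satisfy 1 <= k <= N - 1; got k = ", k, ", N = ", N,
         call. = FALSE)
  }
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    stop("v must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    stop("sd must be a single positive number", call. = FALSE)
  }
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  structure(list(N = N, k = k, v = v, sd = sd,
                 seed = as.integer(seed), reps = reps),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> N:", x$N, " k:", x$k, " v:", x$v, " sd:", x$sd,
      " seed:", x$seed, " reps:", x$reps, "\n")
  invisible(x)
}

# Deterministic per-(seed, rep, stream) seed, kept inside 32-bit range so
# any single replicate can be replayed in isolation.
rep_seed <- function(seed, rep, stream) {
  base <- (abs(as.double(seed)) %% 1048573) * 2039 +
    as.double(rep) * 613 + as.double(stream)
  as.integer(base %% 2147483647)
}

# Evaluate code under a fixed seed, leaving the caller's RNG state exactly
# as it was.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

gen_step_vec <- function(cfg, rep = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(rep_seed(cfg$seed, rep, 1L), {
    z <- stats::rnorm(cfg$N, mean = 0, sd = cfg$sd)
    z[(cfg$k + 1L):cfg$N] <- z[(cfg$k + 1L):cfg$N] + cfg$v
    z
  })
}

gen_ref_vec <- function(cfg, rep = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(rep_seed(cfg$seed, rep, 2L),
                  stats::rnorm(cfg$N, mean = 0, sd = cfg$sd))
}

#' Generate one diagnosed mean-shift series
#'
#' Samples `1..k` are i.i.d. N(0, sd^2); samples `k+1..N` are
#' N(v, sd^2). The RNG is seeded deterministically from `(seed, rep)`, so
#' any single replicate is reproducible in isolation and the caller's RNG
#' state is left untouched.
#'
#' @param cfg A [sim_config()].
#' @param rep Replicate number (1-based).
#' @return A tibble with columns `index` and `z`.
#' @export
gen_step_series <- function(cfg, rep = 1) {
  z <- gen_step_vec(cfg, rep)
  tibble::tibble(index = seq_along(z), z = z)
}

#' Generate a reference/diagnosed series pair
#'
#' The reference `x` is an independent length-`N` draw from the null model
#' N(0, sd^2) (an independent sub-stream of the same `(seed, rep)`), the
#' diagnosed `z` is the mean-shift series of [gen_step_series()].
#'
#' @inheritParams gen_step_series
#' @return A tibble with columns `index`, `x`, `z`.
#' @export
gen_pair <- function(cfg, rep = 1) {
  tibble::tibble(index = seq_len(cfg$N),
                 x = gen_ref_vec(cfg, rep),
                 z = gen_step_vec(cfg, rep))
}

ecg_template <- function(N) {
  period <- max(8L, N %/% 16L)
  phase <- ((seq_len(N) - 1L) %% period) / period
  # stylised beat: sharp positive spike with a shallow repolarisation dip
  exp(-0.5 * ((phase - 0.30) / 0.035)^2) -
    0.25 * exp(-0.5 * ((phase - 0.55) / 0.10)^2)
}

#' Generate an ECG-like regime-switch fixture
#'
#' A synthetic quasi-periodic spike-train pair emulating the
#' assembled-sample protocol for heartbeat-like data: the reference is a
#' clean waveform (fixed beat template, period about `N / 16`, small
#' Gaussian jitter), and the diagnosed series follows the same waveform up
#' to sample `k`, after which the beat amplitude is scaled by 2.5 and
#' broadband noise (sd 0.5) is added, emulating a noise-stressed abnormal
#' regime. With `k = N` the diagnosed series has no abnormal part. This is
#' a shape emulation for exercising the detection protocol, not a cardiac
#' electrophysiology simulator.
#'
#' @param N Power-of-two series length.
#' @param k Switch position, `1 <= k <= N`.
#' @param seed Integer seed.
#' @return A tibble with columns `index`, `x`, `z`.
#' @export
gen_ecg_fixture <- function(N, k, seed = 0) {
  N <- as.integer(N)
  k <- as.integer(k)
  if (N < 16L || bitwAnd(N, N - 1L) != 0L) {
    stop("N must be a power of two >= 16; got ", N, call. = FALSE)
  }
  if (k < 1L || k > N) {
    stop("k must satisfy 1 <= k <= N", call. = FALSE)
  }
  with_local_seed(rep_seed(seed, 1L, 3L), {
    w <- ecg_template(N)
    x <- w + stats::rnorm(N, sd = 0.02)
    z <- w + stats::rnorm(N, sd = 0.02)
    if (k < N) {
      abn <- (k + 1L):N
      z[abn] <- 2.5 * w[abn] + stats::rnorm(length(abn), sd = 0.5)
    }
    tibble::tibble(index = seq_len(N), x = x, z = z)
  })
}
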