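accuracy_from_error <- function(mean_err, N) 1 - abs(mean_err) / N

detector_for <- function(method) {
  switch(method,
         hwks = function(x, z) detect_hwks(x, z)$est_cp,
         ks = function(x, z) detect_ks_scan(z)$est_cp,
         hw = function(x, z) detect_hw_onelevel(z)$est_cp,
         t = function(x, z) detect_welch_t(z)$est_cp,
         stop("unknown method \"", method, "\"", call. = FALSE))
}

#' Run one Monte-Carlo benchmark cell
#'
#' Runs `cfg$reps` seeded replicates of [gen_pair()] followed by the chosen
#' detector and summarises them: `mean_err` is the mean signed error
#' `est_cp - k`, `abs_err = |mean_err|`, `accuracy = 1 - abs_err / N`, and
#' `hit` is the fraction of replicates with `est_cp == k` exactly.
#'
#' @param method One of `"hwks"`, `"ks"`, `"hw"`, `"t"`.
#' @param cfg A [sim_config()].
#' @return A one-row tibble (a metric record) with columns `method`, `N`,
#'   `k`, `v`, `reps`, `mean_err`, `abs_err`, `accuracy`, `hit`.
#' @export
run_cell <- function(method, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  detect <- detector_for(method)
  est <- vapply(seq_len(cfg$reps), function(r) {
    x <- gen_ref_vec(cfg, r)
    z <- gen_step_vec(cfg, r)
    detect(x, z)
  }, numeric(1))
  mean_err <- mean(est - cfg$k)
  tibble::tibble(
    method = method, N = cfg$N, k = cfg$k, v = cfg$v, reps = cfg$reps,
    mean_err = mean_err, abs_err = abs(mean_err),
    accuracy = accuracy_from_error(mean_err, cfg$N),
    hit = mean(est == cfg$k))
}

#' Preset benchmark design grids
#'
#' The standard eight-cell mean-shift design used throughout the package:
#' sizes `N = 2^3 .. 2^10` with boundary-adjacent change points
#' `k = 2, 3, 5, 9, 113, 225, 449, 897` and shift `v = 2` at `sd = 1`.
#' `"single"` is the same grid with one replicate per cell.
#'
#' @param preset `"standard"` (600 replicates per cell) or `"single"`.
#' @param seed Base seed for every cell.
#' @param reps Replicates per cell; defaults to the preset's convention.
#' @param v,sd Shift and noise level for every cell.
#' @return A tibble of design cells suitable for [run_benchmark()].
#' @export
benchmark_preset <- function(preset = c("standard", "single"), seed = 0,
                             reps = NULL, v = 2, sd = 1) {
  preset <- match.arg(preset)
  if (is.null(reps)) reps <- if (preset == "standard") 600L else 1L
  tibble::tibble(
    N = 2L^(3:10),
    k = c(2L, 3L, 5L, 9L, 113L, 225L, 449L, 897L),
    v = v, sd = sd, seed = as.integer(seed), reps = as.integer(reps))
}

#' Run a Monte-Carlo benchmark over methods and design cells
#'
#' Evaluates every method on every design cell via [run_cell()] and
#' appends one averaged row per method holding the arithmetic means over
#' cells of `abs_err`, `accuracy` and `hit` (the summary convention of the
#' per-method "averaged" column). Optionally writes the table as TSV (with
#' the fixed column order `method, N, k, v, reps, mean_err, abs_err,
#' accuracy, hit`) and JSON.
#'
#' @param configs A data frame of design cells with columns `N`, `k`, `v`,
#'   `sd`, `seed`, `reps` (e.g. from [benchmark_preset()]), or a list of
#'   [sim_config()] objects.
#' @param methods Character vector of method tags.
#' @param out Optional output path stem; writes `<out>.tsv` and
#'   `<out>.json`.
#' @param progress Emit one message per cell to stderr.
#' @return A tibble of metric records with an extra column `row` marking
#'   `"config"` and `"averaged"` rows (the `row` column is not written to
#'   the TSV).
#' @export
run_benchmark <- function(configs, methods = c("hwks", "ks", "hw", "t"),
                          out = NULL, progress = FALSE) {
  if (is.data.frame(configs)) {
    configs <- purrr::pmap(configs, function(N, k, v, sd = 1, seed = 0,
                                             reps = 1, ...) {
      sim_config(N = N, k = k, v = v, sd = sd, seed = seed, reps = reps)
    })
  }
  if (length(configs) == 0L || length(methods) == 0L) {
    stop("need at least one method and one config", call. = FALSE)
  }
  stopifnot(all(vapply(configs, inherits, TRUE, "sim_config")))
  records <- purrr::map_dfr(methods, function(m) {
    purrr::map_dfr(configs, function(cfg) {
      if (progress) {
        message(sprintf("cell method=%s N=%d k=%d reps=%d",
                        m, cfg$N, cfg$k, cfg$reps))
      }
      run_cell(m, cfg)
    })
  })
  averaged <- records |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      N = NA_integer_, k = NA_integer_, v = NA_real_,
      reps = sum(.data$reps),
      mean_err = NA_real_,
      abs_err = mean(.data$abs_err),
      accuracy = mean(.data$accuracy),
      hit = mean(.data$hit), .groups = "drop") |>
    dplyr::select(dplyr::all_of(names(records)))
  result <- dplyr::bind_rows(
    dplyr::mutate(records, row = "config"),
    dplyr::mutate(averaged, row = "averaged"))
  class(result) <- c("hwks_benchmark", class(result))
  if (!is.null(out)) {
    cols <- c("method", "N", "k", "v", "reps", "mean_err", "abs_err",
              "accuracy", "hit")
    readr::write_tsv(result[, cols], paste0(out, ".tsv"))
    jsonlite::write_json(result, paste0(out, ".json"),
                         dataframe = "rows", digits = NA, na = "null")
  }
  result
}

#' Plot benchmark metrics across sample sizes
#'
#' @param object A benchmark table from [run_benchmark()].
#' @param metric One of `"abs_err"`, `"accuracy"`, `"hit"`, `"mean_err"`.
#' @param ... Unused.
#' @return A ggplot of the metric against `N` (log2 axis), one line per
#'   method.
#' @export
autoplot.hwks_benchmark <- function(object, metric = "accuracy", ...) {
  plot_benchmark(object, metric)
}

#' @rdname autoplot.hwks_benchmark
#' @param table A benchmark table from [run_benchmark()].
#' @export
plot_benchmark <- function(table, metric = c("accuracy", "abs_err", "hit",
                                             "mean_err")) {
  metric <- match.arg(metric)
  cells <- dplyr::filter(table, .data$row == "config")
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = .data$N, y = .data[[metric]],
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "series length N", y = metric)
}
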