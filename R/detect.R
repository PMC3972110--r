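new_cp_result <- function(method, n, est_cp, changed, statistic,
                          leaf = NA_integer_, path = NULL, profile = NULL,
                          n_stat_evals = NA_integer_, config = list()) {
  structure(
    list(method = method, n = as.integer(n), est_cp = as.integer(est_cp),
         changed = isTRUE(changed), statistic = statistic,
         leaf = as.integer(leaf), path = path, profile = profile,
         n_stat_evals = as.integer(n_stat_evals), config = config),
    class = "cp_result")
}

#' @export
print.cp_result <- function(x, ...) {
  cat("<cp_result> method:", x$method, "\n")
  cat("  n:", x$n, "  est_cp:", x$est_cp,
      "  changed:", x$changed,
      "  statistic:", format(x$statistic, digits = 5), "\n")
  if (!is.null(x$path)) cat("  search path:", nrow(x$path), "steps\n")
  if (!is.null(x$profile)) cat("  scan profile:", nrow(x$profile), "splits\n")
  invisible(x)
}

#' Root-to-leaf search through the coefficient trees
#'
#' Descends the approximation tree from the root, at each level computing
#' the node statistic [node_rs()] for both children of the current node and
#' selecting the child with the larger statistic (criterion 1). When the
#' two statistics tie (including the common case that both are zero because
#' neither scaled distance clears the threshold), the child with the larger
#' absolute detail coefficient is selected instead (criterion 2, the
#' data-fluctuation criterion); a full tie goes left. Exactly
#' `2 * log2(n)` node statistics are evaluated.
#'
#' @inheritParams scaled_ks_distance
#' @param tca,tcd Approximation and detail `coeff_tree`s built from
#'   `diag_z`.
#' @param cfg A [ks_config()].
#' @return A list with `leaf` (the reached leaf index `b`), `path` (a
#'   tibble of per-level search steps), and `n_stat_evals`.
#' @export
hwks_descend <- function(ref_x, diag_z, tca, tcd, cfg = ks_config()) {
  stopifnot(inherits(tca, "coeff_tree"), inherits(tcd, "coeff_tree"))
  if (tca$n != length(diag_z) || tcd$n != length(diag_z)) {
    stop("trees were not built from diag_z (length mismatch)", call. = FALSE)
  }
  if (length(ref_x) != length(diag_z)) {
    stop("ref_x and diag_z must have the same length", call. = FALSE)
  }
  k <- tca$depth
  b <- 1L
  steps <- vector("list", k)
  n_eval <- 0L
  for (i in seq_len(k)) {
    lev <- k - i
    left <- 2L * b - 1L
    right <- 2L * b
    rs_l <- node_rs(ref_x, diag_z, tca, lev, left, cfg)$rs
    rs_r <- node_rs(ref_x, diag_z, tca, lev, right, cfg)$rs
    n_eval <- n_eval + 2L
    cd_l <- abs(tree_node(tcd, lev, left))
    cd_r <- abs(tree_node(tcd, lev, right))
    if (rs_l > rs_r) {
      b <- left
      crit <- "1"
    } else if (rs_l < rs_r) {
      b <- right
      crit <- "1"
    } else if (cd_l > cd_r) {
      b <- left
      crit <- "2"
    } else if (cd_l < cd_r) {
      b <- right
      crit <- "2"
    } else {
      b <- left
      crit <- "tie-left"
    }
    steps[[i]] <- tibble::tibble(
      level = lev, chosen_position = b,
      rs_left = rs_l, rs_right = rs_r,
      criterion = crit, cd_left_abs = cd_l, cd_right_abs = cd_r)
  }
  list(leaf = b, path = dplyr::bind_rows(steps), n_stat_evals = n_eval)
}

#' Tree-descent change-point detector
#'
#' The full detector: builds the approximation and detail trees from the
#' diagnosed series, runs the root-to-leaf search ([hwks_descend()]) against
#' the reference series, and reports the estimated change point as
#' `b - 1` -- the length of the estimated pre-change segment, where `b` is
#' the reached leaf (with the tie rules the descent lands on the first
#' post-change sample in the clean-step case). The result is floored at 1
#' so that a reported change point always leaves a nonempty pre-change
#' segment. `changed` is `TRUE` when any node statistic along the path is
#' positive, i.e. some scaled distance cleared the threshold `Ca`.
#'
#' @inheritParams scaled_ks_distance
#' @param cfg A [ks_config()].
#' @param fit How to handle non-power-of-two lengths: `"strict"` (refuse),
#'   `"truncate"` or `"reflect"`; see [fit_series_length()].
#' @return A `cp_result` with the search path attached.
#' @examples
#' pair <- gen_pair(sim_config(N = 64, k = 9, v = 4, seed = 1))
#' detect_hwks(pair$x, pair$z)
#' @export
detect_hwks <- function(ref_x, diag_z, cfg = ks_config(),
                        fit = c("strict", "truncate", "reflect")) {
  fit <- match.arg(fit)
  ref_x <- check_series(ref_x)
  diag_z <- check_series(diag_z)
  if (length(ref_x) != length(diag_z)) {
    stop("ref_x and diag_z must have equal length (got ", length(ref_x),
         " and ", length(diag_z), ")", call. = FALSE)
  }
  n_orig <- length(diag_z)
  fz <- fit_series_length(diag_z, fit)
  fx <- suppressWarnings(fit_series_length(ref_x, fit))
  trees <- haar_trees(fz$values)
  desc <- hwks_descend(fx$values, fz$values, trees$tca, trees$tcd, cfg)
  est <- max(1L, desc$leaf - 1L)
  est <- fz$map_index(est)
  est <- max(1L, min(est, n_orig - 1L))
  max_rs <- max(c(desc$path$rs_left, desc$path$rs_right))
  new_cp_result(
    method = "hwks", n = n_orig, est_cp = est,
    changed = max_rs > 0, statistic = max_rs, leaf = desc$leaf,
    path = desc$path, n_stat_evals = desc$n_stat_evals,
    config = list(ca = cfg$ca, alpha = cfg$alpha, fit = fit))
}

#' Fit a series to a power-of-two length
#'
#' The coefficient trees require `n = 2^k`. `"strict"` refuses other
#' lengths; `"truncate"` keeps the leading `2^floor(log2(n))` samples (with
#' a warning); `"reflect"` pads to the next power of two by reflecting the
#' tail (with a warning) and maps detected indices back to the original
#' scale (an index falling inside the padding is folded back onto the
#' original tail).
#'
#' @param values Numeric vector.
#' @param fit `"strict"`, `"truncate"`, or `"reflect"`.
#' @return A list with `values` (fitted series) and `map_index` (a function
#'   mapping an index in the fitted series back to the original series).
#' @export
fit_series_length <- function(values, fit = c("strict", "truncate",
                                              "reflect")) {
  fit <- match.arg(fit)
  n <- length(values)
  k <- floor(log2(n))
  if (2^k == n) {
    return(list(values = values, map_index = identity))
  }
  switch(fit,
    strict = stop("series length ", n, " is not a power of two; ",
                  "pass fit = \"truncate\" or fit = \"reflect\"",
                  call. = FALSE),
    truncate = {
      m <- 2L^k
      warning("truncating series from ", n, " to ", m, " samples",
              call. = FALSE)
      list(values = values[seq_len(m)], map_index = identity)
    },
    reflect = {
      m <- 2L^(k + 1L)
      pad <- m - n
      warning("reflect-padding series from ", n, " to ", m, " samples",
              call. = FALSE)
      padded <- c(values, values[n - seq_len(pad) + 1L])
      list(values = padded,
           map_index = function(i) ifelse(i > n, 2L * n - i + 1L, i))
    })
}

#' Detect a change point in a data frame of series
#'
#' Data-frame front end to the four detectors. The diagnosed series is
#' taken from `value`; the tree-descent method additionally needs a paired
#' reference series of equal length in `reference`.
#'
#' @param data A data frame.
#' @param value Column holding the diagnosed series (tidy-eval).
#' @param reference Column holding the reference series; required for
#'   `method = "hwks"`, ignored by the baselines.
#' @param method One of `"hwks"` (tree descent), `"ks"` (exhaustive scaled
#'   KS split scan), `"hw"` (one-level Haar detail maximum), `"t"` (Welch t
#'   split scan).
#' @param ... Passed on to the underlying detector (`cfg`, `alpha`, `fit`).
#' @return A `cp_result`; see [generics::tidy()] and [generics::glance()]
#'   methods.
#' @examples
#' pair <- gen_pair(sim_config(N = 64, k = 9, v = 4, seed = 1))
#' detect_cp(pair, value = z, reference = x, method = "hwks")
#' detect_cp(pair, value = z, method = "ks")
#' @export
detect_cp <- function(data, value, reference = NULL,
                      method = c("hwks", "ks", "hw", "t"), ...) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data))
  z <- rlang::eval_tidy(rlang::enquo(value), data)
  refq <- rlang::enquo(reference)
  x <- if (rlang::quo_is_null(refq)) NULL else rlang::eval_tidy(refq, data)
  if (method == "hwks") {
    if (is.null(x)) {
      stop("method \"hwks\" needs a reference series", call. = FALSE)
    }
    detect_hwks(x, z, ...)
  } else {
    switch(method,
           ks = detect_ks_scan(z, ...),
           hw = detect_hw_onelevel(z, ...),
           t = detect_welch_t(z, ...))
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a detection result
#'
#' For the tree-descent detector the tidy form is the per-level search
#' path; for the scan baselines it is the split-statistic profile.
#'
#' @param x A `cp_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cp_result <- function(x, ...) {
  if (!is.null(x$path)) return(x$path)
  if (!is.null(x$profile)) return(x$profile)
  tibble::tibble(est_cp = x$est_cp, changed = x$changed,
                 statistic = x$statistic)
}

#' One-row summary of a detection result
#'
#' @param x A `cp_result`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `n`, `est_cp`, `changed`,
#'   `statistic`, and `n_stat_evals`.
#' @export
glance.cp_result <- function(x, ...) {
  tibble::tibble(method = x$method, n = x$n, est_cp = x$est_cp,
                 changed = x$changed, statistic = x$statistic,
                 n_stat_evals = x$n_stat_evals)
}

#' Plot a detection result
#'
#' Scan methods show the statistic profile over candidate splits; the
#' tree-descent method shows the node statistics along the search path by
#' level. The estimated change point is marked.
#'
#' @param object A `cp_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cp_result <- function(object, ...) {
  if (!is.null(object$profile)) {
    p <- ggplot2::ggplot(object$profile,
                         ggplot2::aes(x = .data$split, y = .data$statistic)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = object$est_cp, linetype = 2,
                          colour = "red") +
      ggplot2::labs(x = "candidate split m", y = "statistic",
                    title = paste0(object$method, ": est_cp = ",
                                   object$est_cp))
    return(p)
  }
  path <- tidyr::pivot_longer(object$path, c("rs_left", "rs_right"),
                              names_to = "child", values_to = "rs")
  ggplot2::ggplot(path, ggplot2::aes(x = .data$level, y = .data$rs,
                                     colour = .data$child)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "tree level (root to leaves)", y = "node statistic RS",
                  title = paste0("hwks: est_cp = ", object$est_cp))
}

#' Plot a series with its detected change point
#'
#' @param data Data frame with the series.
#' @param value Column holding the series (tidy-eval).
#' @param result A `cp_result` for that series.
#' @return A ggplot.
#' @export
plot_series_cp <- function(data, value, result) {
  stopifnot(is.data.frame(data), inherits(result, "cp_result"))
  z <- rlang::eval_tidy(rlang::enquo(value), data)
  df <- tibble::tibble(index = seq_along(z), value = z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = result$est_cp + 0.5, linetype = 2,
                        colour = "red") +
    ggplot2::labs(title = paste0(result$method, ": change after index ",
                                 result$est_cp))
}
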