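#' One level of the orthonormal Haar transform
#'
#' Splits a series of even length `n` into a trend (pairwise scaled average)
#' and a fluctuation (pairwise scaled difference) sub-series, each of length
#' `n / 2`. The orthonormal `1/sqrt(2)` scaling is used throughout the
#' package, so squared signal energy is conserved exactly:
#' `sum(values^2) == sum(trend^2) + sum(fluct^2)`.
#'
#' @param values Numeric vector of finite values with even length.
#' @return A list with components `trend` and `fluct`, numeric vectors of
#'   length `length(values) / 2`. The fluctuation sign convention is
#'   left-minus-right: `fluct[j] = (values[2j-1] - values[2j]) / sqrt(2)`.
#' @examples
#' haar_step(c(1, 2, 3, 4))
#' @export
haar_step <- function(values) {
  values <- check_series(values)
  n <- length(values)
  if (n %% 2L != 0L) {
    stop("haar_step() needs an even-length series; got length ", n,
         call. = FALSE)
  }
  odd <- values[seq(1L, n, by = 2L)]
  even <- values[seq(2L, n, by = 2L)]
  list(trend = (odd + even) / sqrt(2), fluct = (odd - even) / sqrt(2))
}

#' Multi-level Haar decomposition
#'
#' Applies [haar_step()] recursively to the trend of the previous level,
#' retaining every level's trend and fluctuation coefficient vectors (the
#' rows of the coefficient matrices in the multiresolution view of the
#' transform).
#'
#' @param values Numeric vector; `length(values)` must be divisible by
#'   `2^depth`.
#' @param depth Number of levels, between 1 and `log2(length(values))`.
#'   Defaults to the maximal depth the length allows.
#' @return An object of class `haar_decomp`: a list with `n`, `depth`, and
#'   lists `trend` and `fluct` whose i-th elements are the level-i
#'   coefficient vectors of length `n / 2^i`.
#' @examples
#' d <- haar_multilevel(c(1, 2, 3, 4), depth = 2)
#' d$trend[[2]]  # 5
#' d$fluct[[2]]  # -2
#' @export
haar_multilevel <- function(values, depth = NULL) {
  values <- check_series(values)
  n <- length(values)
  max_depth <- floor(log2(n))
  if (is.null(depth)) depth <- max_depth
  depth <- as.integer(depth)
  if (length(depth) != 1L || is.na(depth) || depth < 1L || depth > max_depth) {
    stop("depth must be an integer in [1, ", max_depth, "] for length ", n,
         call. = FALSE)
  }
  if (n %% 2L^depth != 0L) {
    stop("series length ", n, " is not divisible by 2^", depth, call. = FALSE)
  }
  trend <- vector("list", depth)
  fluct <- vector("list", depth)
  cur <- values
  for (i in seq_len(depth)) {
    s <- haar_step(cur)
    trend[[i]] <- s$trend
    fluct[[i]] <- s$fluct
    cur <- s$trend
  }
  structure(list(n = n, depth = depth, trend = trend, fluct = fluct),
            class = "haar_decomp")
}

#' Invert a multi-level Haar decomposition
#'
#' Synthesises the original series from the deepest trend plus the stack of
#' fluctuations, i.e. runs the multiresolution reconstruction. Round-trips
#' [haar_multilevel()] to floating-point accuracy.
#'
#' @param decomp A `haar_decomp` object.
#' @return Numeric vector of length `decomp$n`.
#' @export
haar_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "haar_decomp"))
  cur <- decomp$trend[[decomp$depth]]
  for (i in rev(seq_len(decomp$depth))) {
    d <- decomp$fluct[[i]]
    if (length(d) != length(cur)) {
      stop("inconsistent level lengths at level ", i, call. = FALSE)
    }
    up <- numeric(2L * length(cur))
    up[seq(1L, length(up), by = 2L)] <- (cur + d) / sqrt(2)
    up[seq(2L, length(up), by = 2L)] <- (cur - d) / sqrt(2)
    cur <- up
  }
  if (length(cur) != decomp$n) {
    stop("reconstruction length mismatch", call. = FALSE)
  }
  cur
}

#' Build the approximation and detail coefficient trees
#'
#' Constructs the two binary coefficient trees used by the tree-descent
#' detector: the approximation tree (trend coefficients) and the detail tree
#' (fluctuation coefficients). Level 0 of either tree holds the original
#' samples; a node at level `l` covers a block of `2^l` consecutive samples.
#'
#' @param values Numeric vector whose length is an exact power of two
#'   (`n = 2^k`, `k >= 1`). Other lengths are refused; see
#'   [fit_series_length()] for the truncate/reflect directives.
#' @return A list with elements `tca` and `tcd`, each a `coeff_tree`.
#' @examples
#' tr <- haar_trees(c(1, 2, 3, 4))
#' tree_node(tr$tca, 2, 1)  # 5
#' tree_node(tr$tcd, 2, 1)  # -2
#' @export
haar_trees <- function(values) {
  values <- check_series(values)
  n <- length(values)
  k <- round(log2(n))
  if (n < 2L || 2L^k != n) {
    stop("haar_trees() needs a power-of-two length (got ", n, "); ",
         "use fit_series_length() to truncate or reflect-pad first",
         call. = FALSE)
  }
  d <- haar_multilevel(values, depth = k)
  new_tree <- function(kind, levels) {
    structure(list(kind = kind, depth = k, n = n, levels = levels),
              class = "coeff_tree")
  }
  list(tca = new_tree("approximation", c(list(values), d$trend)),
       tcd = new_tree("detail", c(list(values), d$fluct)))
}

#' @export
print.coeff_tree <- function(x, ...) {
  cat("<coeff_tree> kind:", x$kind, " depth:", x$depth, " n:", x$n, "\n")
  invisible(x)
}

check_node <- function(tree, level, position) {
  stopifnot(inherits(tree, "coeff_tree"))
  level <- as.integer(level)
  position <- as.integer(position)
  if (level < 0L || level > tree$depth) {
    stop("level ", level, " out of range [0, ", tree$depth, "]",
         call. = FALSE)
  }
  if (position < 1L || position > tree$n / 2L^level) {
    stop("position ", position, " out of range [1, ", tree$n / 2L^level,
         "] at level ", level, call. = FALSE)
  }
  list(level = level, position = position)
}

#' Coefficient tree node and block accessors
#'
#' `tree_node()` returns the coefficient stored at `(level, position)`
#' (level 0 nodes are the original samples). `tree_block()` returns the
#' 1-based inclusive range of sample indices covered by that node,
#' `[(position - 1) * 2^level + 1, position * 2^level]`.
#'
#' @param tree A `coeff_tree` from [haar_trees()].
#' @param level Integer level, 0 (leaves) to `tree$depth` (root).
#' @param position Integer position within the level, 1-based.
#' @return `tree_node()`: a single numeric; `tree_block()`: an integer
#'   vector `c(first, last)`.
#' @export
tree_node <- function(tree, level, position) {
  id <- check_node(tree, level, position)
  tree$levels[[id$level + 1L]][id$position]
}

#' @rdname tree_node
#' @export
tree_block <- function(tree, level, position) {
  id <- check_node(tree, level, position)
  c((id$position - 1L) * 2L^id$level + 1L, id$position * 2L^id$level)
}

#' Block mean recovered from an approximation-tree node
#'
#' With the orthonormal scaling, an approximation coefficient at level `l`
#' equals `2^(l/2)` times the arithmetic mean of the samples in its block,
#' so the mean is recovered exactly as `2^(-l/2) * node`. These block means
#' are the probe points of the node statistic ([node_rs()]).
#'
#' @inheritParams tree_node
#' @return The arithmetic mean of the covered samples.
#' @export
block_mean <- function(tree, level, position) {
  if (!identical(tree$kind, "approximation")) {
    stop("block_mean() is defined for the approximation tree", call. = FALSE)
  }
  2^(-level / 2) * tree_node(tree, level, position)
}

check_series <- function(values, min_len = 2L) {
  if (is.data.frame(values)) {
    stop("expected a numeric vector; data-frame front ends are detect_cp(), ",
         "gen_* and run_benchmark()", call. = FALSE)
  }
  values <- as.numeric(values)
  if (length(values) < min_len) {
    stop("series must have at least ", min_len, " values", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    stop("non-finite value at index ", bad, call. = FALSE)
  }
  values
}
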