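#' Read a single-channel series from a text file
#'
#' Accepts plain text, CSV or TSV with one numeric value per line. A single
#' non-numeric first line is treated as a header and skipped. Any missing
#' or non-numeric value aborts with the offending line number.
#'
#' @param path File path.
#' @return A tibble with columns `index` and `value`.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lineno <- seq_along(lines)
  nonempty <- nzchar(lines)
  lines <- lines[nonempty]
  lineno <- lineno[nonempty]
  if (length(lines) == 0L) stop("empty input: ", path, call. = FALSE)
  # single column possibly terminated by a delimiter; strip it
  lines <- sub("[,;\t ]+$", "", lines)
  vals <- suppressWarnings(as.numeric(lines))
  if (is.na(vals[1L]) && length(lines) > 1L) {
    lines <- lines[-1L]
    lineno <- lineno[-1L]
    vals <- suppressWarnings(as.numeric(lines))
  }
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad) > 0L) {
    stop("non-numeric or missing value at line ", lineno[bad[1L]], " of ",
         path, ": \"", lines[bad[1L]], "\"", call. = FALSE)
  }
  tibble::tibble(index = seq_along(vals), value = vals)
}

#' Write a series to a text file, one value per line
#'
#' @param values Numeric vector or a data frame with a `value`/`z` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(values, path) {
  if (is.data.frame(values)) {
    col <- intersect(c("value", "z", "x"), names(values))[1L]
    if (is.na(col)) stop("no value column found", call. = FALSE)
    values <- values[[col]]
  }
  writeLines(format(values, digits = 17, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

#' Export a Haar decomposition as JSON
#'
#' Debug export of the per-level coefficient arrays.
#'
#' @param decomp A `haar_decomp` from [haar_multilevel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decomposition_json <- function(decomp, path) {
  stopifnot(inherits(decomp, "haar_decomp"))
  jsonlite::write_json(
    list(n = decomp$n, depth = decomp$depth,
         trend = decomp$trend, fluct = decomp$fluct),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialise a detection result to JSON
#'
#' @param result A `cp_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detection_json <- function(result, path) {
  stopifnot(inherits(result, "cp_result"))
  out <- list(method = result$method, n = result$n,
              est_cp = result$est_cp, changed = result$changed,
              statistic = result$statistic, config = result$config)
  if (!is.na(result$leaf)) out$leaf <- result$leaf
  if (!is.null(result$path)) out$path <- result$path
  if (!is.null(result$profile)) out$profile <- result$profile
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
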