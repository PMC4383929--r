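# Internal helpers shared across modules.

#' Natural (human) ordering of chromosome-like names
#'
#' Orders names so that embedded integers compare numerically:
#' \code{chr2 < chr10}, \code{block_2 < block_11}.
#'
#' @param x character vector of names.
#' @return integer permutation, as from [order()].
#' @keywords internal
natural_order <- function(x) {
  # split into alternating non-digit / digit chunks, pad digits for lexicographic
  keys <- vapply(x, function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    parts <- vapply(parts, function(p) {
      if (grepl("^[0-9]+$", p)) sprintf("%020d", as.numeric(p)) else p
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
  order(keys, x, method = "radix")
}

abort <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ancora_error")))
}

parse_error <- function(fmt, ...) abort(fmt, ..., class = "ancora_parse_error")
validation_error <- function(fmt, ...) abort(fmt, ..., class = "ancora_validation_error")
usage_error <- function(fmt, ...) abort(fmt, ..., class = "ancora_usage_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert 0-based half-open intervals to 1-based inclusive (GFF3 convention)
#'
#' The package stores every interval 0-based half-open. [to_gff3_coords()] and
#' [from_gff3_coords()] are exact inverses; BED output needs no conversion.
#'
#' @param start,end numeric vectors, 0-based half-open.
#' @return data.frame with 1-based inclusive `start`, `end`.
#' @export
to_gff3_coords <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

#' @rdname to_gff3_coords
#' @export
from_gff3_coords <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}
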