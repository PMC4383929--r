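# Multiple Alignment Format (MAF) blocks.  A block is a set of aligned rows;
# each row records a source sequence ("species.chromosome"), a 0-based
# strand-relative start, the ungapped size, strand, total source length and
# the gapped alignment text.  Negative-strand rows stay in strand-relative
# coordinates as stored; conversion to forward-strand intervals happens only
# when elements are projected (see finalize_cnes).

#' Construct a MAF block
#'
#' @param rows data.frame with columns `src`, `start`, `size`, `strand`,
#'   `srclen`, `text`; `src` is `species.chromosome`.
#' @return object of class `maf_block` with an added `species` and `chrom`
#'   column and `ncol` attribute (alignment width).
#' @export
new_maf_block <- function(rows) {
  stopifnot(all(c("src", "start", "size", "strand", "srclen", "text") %in% names(rows)))
  widths <- nchar(rows$text)
  if (length(unique(widths)) > 1L)
    parse_error("aligned texts have unequal lengths (%s)",
                paste(unique(widths), collapse = ", "))
  ungapped <- nchar(gsub("-", "", rows$text, fixed = TRUE))
  bad <- which(ungapped != rows$size)
  if (length(bad))
    parse_error("row %s: ungapped length %d != declared size %d",
                rows$src[bad[1L]], ungapped[bad[1L]], rows$size[bad[1L]])
  dot <- regexpr(".", rows$src, fixed = TRUE)
  rows$species <- ifelse(dot > 0, substr(rows$src, 1L, dot - 1L), rows$src)
  rows$chrom <- ifelse(dot > 0, substr(rows$src, dot + 1L, nchar(rows$src)), "")
  rownames(rows) <- NULL
  structure(list(rows = rows, ncol = widths[1L] %||% 0L), class = "maf_block")
}

#' @export
print.maf_block <- function(x, ...) {
  cat(sprintf("MAF block: %d rows x %d columns (%s)\n", nrow(x$rows), x$ncol,
              paste(utils::head(x$rows$species, 5), collapse = ", ")))
  invisible(x)
}

#' Read MAF alignment blocks
#'
#' Standard MAF dialect: an `a` line opens a block, `s` lines carry rows
#' (source, 0-based strand-relative start, ungapped size, strand, source
#' length, gapped text).  Other line types (`i`, `e`, `q`, track headers) are
#' ignored.  Row text is preserved verbatim.
#'
#' @param path MAF file.
#' @return list of `maf_block` in file order.
#' @export
read_maf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  current <- NULL
  flush <- function() {
    if (!is.null(current) && length(current)) {
      rows <- do.call(rbind, current)
      blocks[[length(blocks) + 1L]] <<- tryCatch(
        new_maf_block(rows),
        ancora_parse_error = function(e)
          parse_error("block %d: %s", length(blocks) + 1L, conditionMessage(e)))
    }
    current <<- NULL
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      flush()
      current <- list()
    } else if (startsWith(ln, "s ")) {
      if (is.null(current)) parse_error("'s' line outside a block")
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) != 7L) parse_error("malformed 's' line: %s", ln)
      current[[length(current) + 1L]] <- data.frame(
        src = f[2L], start = as.numeric(f[3L]), size = as.numeric(f[4L]),
        strand = f[5L], srclen = as.numeric(f[6L]), text = f[7L],
        stringsAsFactors = FALSE)
    }
  }
  flush()
  blocks
}

#' Write MAF blocks
#'
#' Round-trips with [read_maf()]: column texts are reproduced byte-identically.
#'
#' @param blocks list of `maf_block`.
#' @param path output file.
#' @param header_comment optional comment lines (written with leading `#`).
#' @export
write_maf <- function(blocks, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  for (b in blocks) {
    writeLines("a", con)
    r <- b$rows
    writeLines(sprintf("s %s %s %s %s %s %s", r$src,
                       format(r$start, scientific = FALSE, trim = TRUE),
                       format(r$size, scientific = FALSE, trim = TRUE),
                       r$strand,
                       format(r$srclen, scientific = FALSE, trim = TRUE),
                       r$text), con)
    writeLines("", con)
  }
  invisible(path)
}

# Character matrix of a block: rows x alignment columns.
maf_char_matrix <- function(block) {
  do.call(rbind, strsplit(block$rows$text, "", fixed = TRUE))
}
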