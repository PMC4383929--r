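# MAF simulator with planted conserved elements.  The reference row is an
# ungapped random sequence; every other species copies it inside planted
# intervals and, outside them, mutates each column independently and may
# replace it with a gap.  Because the reference row carries no gaps,
# alignment columns and reference coordinates coincide, which makes the
# recorded truth intervals exact.

#' Simulate a MAF alignment with planted conserved elements
#'
#' @param ref_length reference sequence length (bp).
#' @param n_species total number of species including the reference.
#' @param background_mismatch per-column probability that a non-reference row
#'   carries a different base outside planted intervals; choose it high
#'   enough (e.g. 0.5) that flank columns stay below the identity threshold.
#' @param planted data.frame of perfectly conserved intervals (`start`,
#'   `end`, 0-based half-open on the reference) or list of `c(start, length)`
#'   pairs; intervals must be pairwise separated by at least 4 columns.
#' @param gap_rate per-column probability of a gap in a non-reference row
#'   outside planted intervals (default 0.05).
#' @param cds optional data.frame (`start`, `end`) of coding intervals on the
#'   reference, returned as the reference species' annotation; planted
#'   elements overlapping it are kept (downstream exclusion is the caller's
#'   contract to test).
#' @param seed integer seed.
#' @param ref_species reference species name (default `"hsa"`).
#' @param block_size maximal columns per MAF block; longer alignments are
#'   split into consecutive blocks (default: one block).
#' @return object of class `simulated_alignment`: list with `blocks` (list of
#'   `maf_block`), `truth` (data.frame `chrom`, `start`, `end`),
#'   `annotations` (named list of per-species CDS data.frames, possibly
#'   empty) and `ref_species`.
#' @export
simulate_maf_truth <- function(ref_length, n_species, background_mismatch,
                               planted = NULL, gap_rate = 0.05, cds = NULL,
                               seed, ref_species = "hsa", block_size = Inf) {
  set.seed(seed)
  planted <- normalize_planted(planted, ref_length)
  species <- c(ref_species, sprintf("sp%02d", seq_len(n_species - 1L) + 1L))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ref_length, replace = TRUE)
  in_planted <- rep(FALSE, ref_length)
  for (i in seq_len(nrow(planted)))
    in_planted[(planted$start[i] + 1L):planted$end[i]] <- TRUE
  rows <- matrix("", n_species, ref_length)
  rows[1L, ] <- ref
  for (s in seq_len(n_species - 1L) + 1L) {
    x <- ref
    mut <- !in_planted & stats::runif(ref_length) < background_mismatch
    if (any(mut))
      x[mut] <- vapply(ref[mut], function(b) sample(setdiff(bases, b), 1L),
                       character(1))
    gap <- !in_planted & stats::runif(ref_length) < gap_rate
    x[gap] <- "-"
    rows[s, ] <- x
  }
  srclen <- c(ref_length, vapply(seq_len(n_species - 1L) + 1L, function(s)
    sum(rows[s, ] != "-"), numeric(1)))
  starts <- if (is.finite(block_size))
    seq(0, ref_length - 1L, by = block_size) else 0
  blocks <- list()
  nongap_before <- rep(0, n_species)
  for (b0 in starts) {
    b1 <- min(ref_length, b0 + block_size)
    texts <- apply(rows[, (b0 + 1L):b1, drop = FALSE], 1L, paste, collapse = "")
    sizes <- nchar(gsub("-", "", texts, fixed = TRUE))
    blocks[[length(blocks) + 1L]] <- new_maf_block(data.frame(
      src = paste0(species, ".chr1"), start = nongap_before, size = sizes,
      strand = "+", srclen = srclen, text = texts, stringsAsFactors = FALSE))
    nongap_before <- nongap_before + sizes
  }
  annotations <- list()
  if (!is.null(cds) && nrow(cds))
    annotations[[ref_species]] <- data.frame(chrom = "chr1", start = cds$start,
                                             end = cds$end, stringsAsFactors = FALSE)
  structure(list(blocks = blocks,
                 truth = if (nrow(planted))
                   data.frame(chrom = "chr1", start = planted$start,
                              end = planted$end, stringsAsFactors = FALSE)
                 else data.frame(chrom = character(), start = numeric(),
                                 end = numeric()),
                 annotations = annotations, ref_species = ref_species),
            class = "simulated_alignment")
}

normalize_planted <- function(planted, ref_length) {
  if (is.null(planted))
    return(data.frame(start = numeric(), end = numeric()))
  if (!is.data.frame(planted)) {
    planted <- do.call(rbind, lapply(planted, function(p)
      data.frame(start = p[1L], end = p[1L] + p[2L])))
  }
  if (!"end" %in% names(planted)) planted$end <- planted$start + planted$length
  planted <- planted[order(planted$start), , drop = FALSE]
  if (nrow(planted)) {
    if (any(planted$start < 0) || any(planted$end > ref_length) ||
        any(planted$start >= planted$end))
      validation_error("planted intervals must lie within [0, ref_length)")
    if (nrow(planted) > 1L) {
      sep <- planted$start[-1L] - planted$end[-nrow(planted)]
      if (any(sep < 0)) validation_error("overlapping planted intervals")
      if (any(sep < 4)) validation_error("planted intervals must be separated by >= 4 columns")
    }
  }
  rownames(planted) <- NULL
  planted
}

#' @export
print.simulated_alignment <- function(x, ...) {
  cat(sprintf("Simulated alignment: %d block(s), %d planted element(s), ref %s\n",
              length(x$blocks), nrow(x$truth), x$ref_species))
  invisible(x)
}
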