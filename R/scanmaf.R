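# CNE detection on MAF alignments.  A per-column conservation profile is
# computed against the reference row; seeds are maximal runs of conserved
# columns of a minimal length; seeds are extended outward over short runs of
# non-conserved columns; surviving elements are projected onto reference
# forward-strand coordinates, filtered on projected length, species support
# and coding overlap, and named Reg<Spc><7-digit counter>.

#' Per-column conservation profile of a MAF block
#'
#' Identity of a column is the fraction of non-gap rows carrying the
#' reference row's character (case-insensitive); columns where the reference
#' row has a gap get identity 0 and are never conserved.
#'
#' @param block a `maf_block`.
#' @param ref_species reference species (the species part of the row source).
#' @param identity_threshold minimal identity for a column to be conserved
#'   (inclusive; default 0.90).
#' @return object of class `conservation_profile`: data.frame with one row
#'   per alignment column: `rows_present`, `identity`, `conserved`;
#'   attributes `ref_row` (row index) and `identity_threshold`.
#' @export
column_conservation_profile <- function(block, ref_species,
                                        identity_threshold = 0.90) {
  ref_row <- which(block$rows$species == ref_species)[1L]
  if (is.na(ref_row))
    validation_error("reference species '%s' absent from block", ref_species)
  chars <- toupper(maf_char_matrix(block))
  gaps <- chars == "-"
  ref <- chars[ref_row, ]
  rows_present <- colSums(!gaps)
  matches <- colSums(sweep(chars, 2L, ref, `==`) & !gaps)
  identity <- ifelse(rows_present > 0L, matches / rows_present, 0)
  ref_gap <- gaps[ref_row, ]
  identity[ref_gap] <- 0
  profile <- data.frame(rows_present = rows_present, identity = identity,
                        conserved = !ref_gap & identity >= identity_threshold)
  structure(profile, class = c("conservation_profile", "data.frame"),
            ref_row = ref_row, identity_threshold = identity_threshold)
}

#' Detect conserved elements in a conservation profile
#'
#' Seeds are maximal runs of conserved columns with length >=
#' `min_seed_length`.  Each seed is extended outward by bridging runs of at
#' most `max_bridge` consecutive non-conserved columns whenever a conserved
#' column follows; extension stops before any longer non-conserved run.
#' Overlapping or adjacent extended seeds are merged.  Returned intervals
#' start and end on conserved columns.
#'
#' @param profile a `conservation_profile`.
#' @param min_seed_length minimal conserved-run length to seed an element
#'   (default 10).
#' @param max_bridge maximal bridged run of non-conserved columns (default 3).
#' @return data.frame of column intervals (`col_start`, `col_end`,
#'   0-based half-open over alignment columns).
#' @export
detect_elements <- function(profile, min_seed_length = 10, max_bridge = 3) {
  cons <- profile$conserved
  empty <- data.frame(col_start = integer(), col_end = integer())
  if (!any(cons)) return(empty)
  r <- rle(cons)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L            # 1-based inclusive
  runs <- data.frame(start = starts[r$values], end = ends[r$values],
                     len = r$lengths[r$values])          # conserved runs
  # group consecutive conserved runs separated by bridgeable gaps
  if (nrow(runs) > 1L) {
    gap <- runs$start[-1L] - runs$end[-nrow(runs)] - 1L
    new_group <- c(TRUE, gap > max_bridge)
  } else new_group <- TRUE
  group <- cumsum(new_group)
  out <- lapply(split(seq_len(nrow(runs)), group), function(idx) {
    if (max(runs$len[idx]) < min_seed_length) return(NULL)
    data.frame(col_start = runs$start[idx[1L]] - 1L,
               col_end = runs$end[idx[length(idx)]])
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Project a column interval [c0, c1) onto a row's forward-strand source
# coordinates.  Returns c(start, end) 0-based half-open, or NULL when the row
# has no non-gap character inside the interval.
project_columns_to_row <- function(row_chars, row_start, row_strand, row_srclen,
                                   c0, c1) {
  nongap <- row_chars != "-"
  inside <- nongap[(c0 + 1L):c1]
  n_in <- sum(inside)
  if (n_in == 0L) return(NULL)
  offset <- if (c0 > 0L) sum(nongap[seq_len(c0)]) else 0L
  s <- row_start + offset
  e <- s + n_in
  if (row_strand == "-") c(row_srclen - e, row_srclen - s) else c(s, e)
}

#' Filter, project and name conserved elements
#'
#' Each detected column interval is projected onto the reference row's
#' forward-strand coordinates.  Elements are kept when the projected length
#' is at least `min_final_length`, at least `min_species` species have a
#' non-gap character inside the interval, and the element's projected
#' interval is disjoint from the coding annotation of every species for which
#' one is provided (overlap in any annotated species excludes the element).
#' Survivors across all blocks are merged on the reference when they overlap,
#' then named `Reg<code><7-digit counter>` in (chromosome natural order,
#' start) order.
#'
#' @param blocks list of `maf_block`.
#' @param intervals list (parallel to `blocks`) of interval data.frames from
#'   [detect_elements()].
#' @param ref_species reference species name.
#' @param species_code three-letter code used in CNE names (e.g. `"Hsa"`).
#' @param profiles optional list of matching `conservation_profile`s (used
#'   for mean identity; recomputed when omitted).
#' @param annotations optional named list (by species) of coding-interval
#'   data.frames (`chrom`, `start`, `end`, 0-based half-open, forward strand).
#' @param min_final_length minimal projected reference length (default 20).
#' @param min_species minimal number of supporting species (default 8).
#' @param identity_threshold passed to [column_conservation_profile()] when
#'   profiles are recomputed.
#' @return data.frame of CNEs: `name`, `chrom`, `start`, `end`,
#'   `species_count`, `mean_identity`, `block`.
#' @export
finalize_cnes <- function(blocks, intervals, ref_species, species_code,
                          profiles = NULL, annotations = NULL,
                          min_final_length = 20, min_species = 8,
                          identity_threshold = 0.90) {
  if (!grepl("^[A-Z][a-z]{2}$", species_code))
    validation_error("species code must be 3 letters like 'Hsa', got '%s'",
                     species_code)
  recs <- list()
  for (bi in seq_along(blocks)) {
    block <- blocks[[bi]]
    iv <- intervals[[bi]]
    if (is.null(iv) || !nrow(iv)) next
    profile <- if (!is.null(profiles)) profiles[[bi]] else
      column_conservation_profile(block, ref_species, identity_threshold)
    ref_row <- attr(profile, "ref_row")
    chars <- maf_char_matrix(block)
    r <- block$rows
    for (k in seq_len(nrow(iv))) {
      c0 <- iv$col_start[k]; c1 <- iv$col_end[k]
      ref_iv <- project_columns_to_row(chars[ref_row, ], r$start[ref_row],
                                       r$strand[ref_row], r$srclen[ref_row],
                                       c0, c1)
      if (is.null(ref_iv)) next
      if (ref_iv[2L] - ref_iv[1L] < min_final_length) next
      sub <- chars[, (c0 + 1L):c1, drop = FALSE]
      has_char <- apply(sub != "-", 1L, any)
      n_species <- length(unique(r$species[has_char]))
      if (n_species < min_species) next
      excluded <- FALSE
      if (!is.null(annotations)) {
        for (ri in which(has_char)) {
          cds <- annotations[[r$species[ri]]]
          if (is.null(cds) || !nrow(cds)) next
          ivr <- project_columns_to_row(chars[ri, ], r$start[ri], r$strand[ri],
                                        r$srclen[ri], c0, c1)
          hit <- cds$chrom == r$chrom[ri] & cds$start < ivr[2L] & ivr[1L] < cds$end
          if (any(hit)) { excluded <- TRUE; break }
        }
      }
      if (excluded) next
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = r$chrom[ref_row], start = ref_iv[1L], end = ref_iv[2L],
        species_count = n_species,
        mean_identity = mean(profile$identity[(c0 + 1L):c1]),
        block = bi, stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(data.frame(name = character(), chrom = character(), start = numeric(),
                      end = numeric(), species_count = integer(),
                      mean_identity = numeric(), block = integer(),
                      stringsAsFactors = FALSE))
  cnes <- do.call(rbind, recs)
  cnes <- merge_overlapping_cnes(cnes)
  chrom_levels <- unique(cnes$chrom)[natural_order(unique(cnes$chrom))]
  ord <- order(match(cnes$chrom, chrom_levels), cnes$start, method = "radix")
  cnes <- cnes[ord, , drop = FALSE]
  cnes <- cbind(name = sprintf("Reg%s%07d", species_code, seq_len(nrow(cnes))),
                cnes, stringsAsFactors = FALSE)
  rownames(cnes) <- NULL
  cnes
}

# Union overlapping reference intervals across blocks: merged elements take
# the union interval, the max species count and a length-weighted mean
# identity.
merge_overlapping_cnes <- function(cnes) {
  ord <- order(cnes$chrom, cnes$start, cnes$end, method = "radix")
  cnes <- cnes[ord, , drop = FALSE]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(cnes))) {
    row <- cnes[i, , drop = FALSE]
    if (!is.null(cur) && row$chrom == cur$chrom && row$start < cur$end) {
      w1 <- cur$end - cur$start; w2 <- row$end - row$start
      cur$mean_identity <- (cur$mean_identity * w1 + row$mean_identity * w2) / (w1 + w2)
      cur$end <- max(cur$end, row$end)
      cur$species_count <- max(cur$species_count, row$species_count)
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- row
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full CNE pipeline on MAF blocks
#'
#' @inheritParams finalize_cnes
#' @inheritParams column_conservation_profile
#' @inheritParams detect_elements
#' @return as [finalize_cnes()].
#' @export
scan_cnes <- function(blocks, ref_species, species_code,
                      identity_threshold = 0.90, min_seed_length = 10,
                      max_bridge = 3, min_final_length = 20, min_species = 8,
                      annotations = NULL) {
  profiles <- lapply(blocks, column_conservation_profile,
                     ref_species = ref_species,
                     identity_threshold = identity_threshold)
  intervals <- lapply(profiles, detect_elements,
                      min_seed_length = min_seed_length, max_bridge = max_bridge)
  finalize_cnes(blocks, intervals, ref_species, species_code,
                profiles = profiles, annotations = annotations,
                min_final_length = min_final_length, min_species = min_species,
                identity_threshold = identity_threshold)
}

#' Write CNEs as BED6 (plus a companion TSV)
#'
#' BED score is `round(1000 * mean_identity)`; strand is always `+` (CNEs are
#' reported on the reference forward strand).
#'
#' @param cnes data.frame from [finalize_cnes()].
#' @param path output BED file; the companion TSV (species_count, identity)
#'   is written next to it with extension `.tsv` unless `tsv_path` is given.
#' @param tsv_path optional explicit companion path.
#' @param header_comment optional comment lines (written with leading `#`).
#' @export
write_cnes_bed <- function(cnes, path, tsv_path = NULL, header_comment = NULL) {
  con <- file(path, "w")
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  if (nrow(cnes))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t+", cnes$chrom,
                       as.integer(cnes$start), as.integer(cnes$end), cnes$name,
                       as.integer(round(1000 * cnes$mean_identity))), con)
  close(con)
  tsv <- tsv_path %||% sub("\\.bed$", ".tsv", path)
  con <- file(tsv, "w")
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  writeLines("name\tchrom\tstart\tend\tspecies_count\tmean_identity", con)
  if (nrow(cnes))
    writeLines(sprintf("%s\t%s\t%d\t%d\t%d\t%.6f", cnes$name, cnes$chrom,
                       as.integer(cnes$start), as.integer(cnes$end),
                       as.integer(cnes$species_count), cnes$mean_identity), con)
  close(con)
  invisible(path)
}
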