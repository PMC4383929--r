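# Genome: ordered, oriented gene lists per chromosome for one species.
# Backed by a single data.frame sorted by (chromosome natural order, start,
# gene_id); all coordinates are 0-based half-open.

#' Construct a genome from a gene placement table
#'
#' @param species species name.
#' @param genes data.frame with columns `gene_id`, `family_id`, `chromosome`,
#'   `start`, `end`, `strand` and optionally further annotation columns.
#' @return object of class `genome`: list with `species`, `genes` (sorted) and
#'   `chromosomes` (names in natural order).
#' @export
new_genome <- function(species, genes) {
  required <- c("gene_id", "family_id", "chromosome", "start", "end", "strand")
  missing <- setdiff(required, names(genes))
  if (length(missing))
    validation_error("gene table lacks columns: %s", paste(missing, collapse = ", "))
  if (nrow(genes)) {
    bad <- which(!(genes$start >= 0 & genes$start < genes$end))
    if (length(bad))
      validation_error("invalid interval (need 0 <= start < end) for gene %s",
                       genes$gene_id[bad[1L]])
    if (!all(genes$strand %in% c("+", "-")))
      validation_error("strand must be '+' or '-'")
    dup <- genes$gene_id[duplicated(genes$gene_id)]
    if (length(dup))
      validation_error("duplicate gene ids: %s", paste(unique(dup), collapse = ", "))
  }
  chroms <- unique(genes$chromosome)
  chroms <- chroms[natural_order(chroms)]
  genes$chromosome <- factor(genes$chromosome, levels = chroms)
  ord <- order(as.integer(genes$chromosome), genes$start,
               genes$gene_id, method = "radix")
  genes <- genes[ord, , drop = FALSE]
  genes$chromosome <- as.character(genes$chromosome)
  rownames(genes) <- NULL
  structure(list(species = species, genes = genes, chromosomes = chroms),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("Genome of %s: %d genes on %d chromosomes\n",
              x$species, nrow(x$genes), length(x$chromosomes)))
  invisible(x)
}

#' Genes of one chromosome, in coordinate order
#' @param genome a `genome`.
#' @param chromosome chromosome name.
#' @export
genome_chromosome <- function(genome, chromosome) {
  genome$genes[genome$genes$chromosome == chromosome, , drop = FALSE]
}

#' Read a tab-separated gene position table
#'
#' Expected columns (with a header line): `chromosome`, `start`, `end`,
#' `strand`, `gene_id`, `family_id`, plus optional `key=value` annotation
#' pairs in a trailing column.  Coordinates are 0-based half-open.  Rows are
#' re-sorted by start within each chromosome; duplicate gene ids are rejected.
#'
#' @param path file path.
#' @param species species name stored in the genome.
#' @return a `genome`.
#' @export
read_gene_table <- function(path, species) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) parse_error("empty gene table: %s", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1]]
  required <- c("chromosome", "start", "end", "strand", "gene_id", "family_id")
  if (!all(required %in% header))
    parse_error("gene table header must contain: %s", paste(required, collapse = ", "))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(rows)
  bad <- which(nf < length(header))
  if (length(bad))
    parse_error("malformed row at line %d of %s (%d fields, expected %d)",
                bad[1L] + 1L, path, nf[bad[1L]], length(header))
  tab <- as.data.frame(do.call(rbind, lapply(rows, `[`, seq_along(header))),
                       stringsAsFactors = FALSE)
  names(tab) <- header
  start <- suppressWarnings(as.numeric(tab$start))
  end <- suppressWarnings(as.numeric(tab$end))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    parse_error("non-numeric coordinates at line %d of %s", bad[1L] + 1L, path)
  genes <- data.frame(gene_id = tab$gene_id, family_id = tab$family_id,
                      chromosome = tab$chromosome, start = start, end = end,
                      strand = tab$strand, stringsAsFactors = FALSE)
  extra <- setdiff(header, c(required))
  for (col in extra) genes[[col]] <- tab[[col]]
  new_genome(species, genes)
}

#' Write a genome as a tab-separated gene table
#'
#' Inverse of [read_gene_table()]: reading the written file back yields a
#' genome with identical placements.
#'
#' @param genome a `genome`.
#' @param path output file.
#' @param header_comment optional comment lines (without leading `#`).
#' @export
write_gene_table <- function(genome, path, header_comment = NULL) {
  g <- genome$genes
  core <- c("chromosome", "start", "end", "strand", "gene_id", "family_id")
  cols <- c(core, setdiff(names(g), core))
  out <- g[, cols, drop = FALSE]
  # integral coordinates print without decimal point
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Adjacent signed gene pairs of a genome
#'
#' Utility used by tests and the simulator: the set of oriented adjacencies
#' (canonical keys, see [adjacency_key()]) realised on the chromosomes of a
#' genome, with genes labelled by `label_col`.
#'
#' @param genome a `genome`.
#' @param label_col column of the gene table used as the gene label.
#' @return character vector of canonical adjacency keys.
#' @export
genome_adjacency_set <- function(genome, label_col = "gene_id") {
  keys <- character()
  for (chrom in genome$chromosomes) {
    g <- genome_chromosome(genome, chrom)
    if (nrow(g) < 2L) next
    lab <- g[[label_col]]
    keys <- c(keys, adjacency_keys_from_sequence(lab, g$strand))
  }
  unique(keys)
}
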