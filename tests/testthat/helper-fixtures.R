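# Shared fixtures: a 4-species toy tree, quick builders for genomes, MAF
# blocks and adjacency graphs.  Everything is built in code; no binary data.

toy_tree <- function() {
  read_species_tree("((human,chimp)Hominidae,(cat,dog)Carnivora)Boreoeutheria;")
}

# A genome from a compact spec: list(chr1 = c("a+", "b-", ...)); coordinates
# are slots of 1000 bp, family defaults to the gene name.
quick_genome <- function(species, chroms, family = NULL) {
  rows <- lapply(names(chroms), function(cn) {
    specs <- chroms[[cn]]
    gene <- sub("[+-]$", "", specs)
    strand <- substring(specs, nchar(specs))
    n <- length(gene)
    data.frame(gene_id = gene,
               family_id = if (is.null(family)) gene else family[gene],
               chromosome = cn, start = (seq_len(n) - 1) * 1000,
               end = (seq_len(n) - 1) * 1000 + 500, strand = strand,
               stringsAsFactors = FALSE)
  })
  new_genome(species, do.call(rbind, rows))
}

# A projected genome literal: list(chr = c("A+", "B-", ...)).
quick_projection <- function(chroms) {
  out <- lapply(chroms, function(specs) {
    data.frame(gene = sub("[+-]$", "", specs),
               orient = substring(specs, nchar(specs)),
               stringsAsFactors = FALSE)
  })
  structure(out, class = "projected_genome")
}

# MAF block from aligned strings; names are "species.chrom" sources.
quick_block <- function(..., starts = NULL, strands = NULL, srclens = NULL) {
  texts <- c(...)
  n <- length(texts)
  sizes <- nchar(gsub("-", "", texts, fixed = TRUE))
  new_maf_block(data.frame(
    src = names(texts),
    start = starts %||% rep(0, n),
    size = sizes,
    strand = strands %||% rep("+", n),
    srclen = srclens %||% (sizes + (starts %||% rep(0, n))),
    text = texts, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adjacency graph literal from edge strings "A+B w" meaning A.head-B.tail
# (signs give the side pair as in a left-to-right reading).
quick_graph <- function(nodes, edges) {
  keys <- vapply(names(edges), function(e) {
    g1 <- sub("^(.+?)([+-])(.+?)([+-])$", "\\1", e)
    o1 <- sub("^(.+?)([+-])(.+?)([+-])$", "\\2", e)
    g2 <- sub("^(.+?)([+-])(.+?)([+-])$", "\\3", e)
    o2 <- sub("^(.+?)([+-])(.+?)([+-])$", "\\4", e)
    adjacency_key(g1, if (o1 == "+") "head" else "tail",
                  g2, if (o2 == "+") "tail" else "head")
  }, character(1))
  adj <- list()
  w <- unlist(edges)
  for (i in seq_along(keys)) {
    for (p in seq_len(w[i])) {
      pk <- sprintf("pair%d", p)
      adj[[pk]] <- c(adj[[pk]] %||% character(), keys[i])
    }
  }
  build_adjacency_graph(adj, nodes)
}

# Flatten contigs to "A+ B- ..." strings for compact expectations.
contig_strings <- function(contigs) {
  vapply(contigs, function(cg) paste0(cg$gene, cg$orient, collapse = " "),
         character(1))
}

# A 10-row block where every column has `match` of 10 rows equal to the
# reference; width columns total.
uniform_block <- function(width, match, n_rows = 10) {
  ref <- strrep("A", width)
  rows <- c(ref, rep(ref, match - 1L),
            rep(strrep("C", width), n_rows - match))
  names(rows) <- paste0(c("hsa", sprintf("sp%02d", seq_len(n_rows - 1L) + 1L)),
                        ".chr1")
  do.call(quick_block, as.list(rows))
}

# Build a block from a conserved/non-conserved column mask: conserved
# columns match the reference in all rows, others only in the reference.
mask_block <- function(mask, n_rows = 10) {
  width <- length(mask)
  ref <- strrep("A", width)
  other <- paste(ifelse(mask, "A", "C"), collapse = "")
  rows <- c(ref, rep(other, n_rows - 1L))
  names(rows) <- paste0(c("hsa", sprintf("sp%02d", seq_len(n_rows - 1L) + 1L)),
                        ".chr1")
  do.call(quick_block, as.list(rows))
}

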