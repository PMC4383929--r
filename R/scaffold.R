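# Round-2 scaffolding and the full reconstruction driver.  Round 2 re-runs
# the adjacency/graph/linearization machinery with round-1 contigs as the
# unit of comparison: each extant chromosome projection is collapsed into a
# sequence of oriented contig occurrences, contig adjacencies conserved in
# informative pairs are combined in a weighted graph, and the linearized
# contig order is expanded back into gene order (scaffolds).

flip_orient <- function(o) ifelse(o == "+", "-", "+")

# Collapse one projected chromosome into oriented contig occurrences.
# gene_info: named list gene -> c(contig_id, position, contig_orient).
collapse_runs <- function(chrom_df, contig_of, pos_of, corient_of) {
  cid <- contig_of[chrom_df$gene]
  keep <- !is.na(cid)
  chrom_df <- chrom_df[keep, , drop = FALSE]
  cid <- cid[keep]
  if (!nrow(chrom_df)) return(data.frame(gene = character(), orient = character(),
                                         stringsAsFactors = FALSE))
  run_id <- cumsum(c(TRUE, cid[-1L] != cid[-length(cid)]))
  genes <- character(); orients <- character()
  for (r in split(seq_along(run_id), run_id)) {
    contig <- cid[r[1L]]
    p <- unname(pos_of[chrom_df$gene[r]])
    o <- chrom_df$orient[r]
    cc <- unname(corient_of[chrom_df$gene[r]])
    fwd <- all(diff(p) == 1L) && all(o == cc)
    rev <- all(diff(p) == -1L) && all(o == flip_orient(cc))
    sign <- if (fwd) "+" else if (rev && length(r) > 1L) "-" else if (length(r) == 1L && o == flip_orient(cc)) "-" else NA
    if (!is.na(sign)) { genes <- c(genes, contig); orients <- c(orients, sign) }
  }
  data.frame(gene = genes, orient = orients, stringsAsFactors = FALSE)
}

#' Scaffold round-1 contigs into final ancestral blocks
#'
#' @param contigs list of round-1 contigs (data.frames `gene`, `orient`).
#' @param projections named list (by species) of `projected_genome` objects
#'   over the ancestor's content.
#' @param pairs data.frame of informative species pairs (`a`, `b`), limited
#'   to species present in `projections`.
#' @return list of scaffolds (data.frames `gene`, `orient`), sorted by
#'   decreasing gene count then first gene id.
#' @export
scaffold_round2 <- function(contigs, projections, pairs) {
  contig_ids <- sprintf("ctg_%06d", seq_along(contigs))
  contig_of <- character(); pos_of <- integer(); corient_of <- character()
  for (k in seq_along(contigs)) {
    cg <- contigs[[k]]
    contig_of[cg$gene] <- contig_ids[k]
    pos_of[cg$gene] <- seq_len(nrow(cg))
    corient_of[cg$gene] <- cg$orient
  }
  contig_proj <- lapply(projections, function(proj) {
    out <- lapply(unclass(proj), collapse_runs,
                  contig_of = contig_of, pos_of = pos_of, corient_of = corient_of)
    out <- out[vapply(out, nrow, integer(1)) > 0L]
    structure(out, class = "projected_genome")
  })
  adj <- list()
  for (i in seq_len(nrow(pairs))) {
    key <- paste(pairs$a[i], pairs$b[i], sep = "~")
    adj[[key]] <- conserved_adjacencies(contig_proj[[pairs$a[i]]],
                                        contig_proj[[pairs$b[i]]])
  }
  graph <- build_adjacency_graph(adj, nodes = contig_ids)
  contig_paths <- linearize_greedy(graph)
  names(contigs) <- contig_ids
  scaffolds <- lapply(contig_paths, function(path) {
    parts <- lapply(seq_len(nrow(path)), function(j) {
      cg <- contigs[[path$gene[j]]]
      if (path$orient[j] == "-") {
        cg <- cg[rev(seq_len(nrow(cg))), , drop = FALSE]
        cg$orient <- flip_orient(cg$orient)
      }
      cg
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
  sort_contigs(scaffolds)
}

#' Reconstruct the gene order of one ancestor
#'
#' Orchestrates the full pipeline: ancestral gene content from the reconciled
#' forest, informative species pairs, projection of each extant genome,
#' conserved adjacencies per pair, weighted adjacency graph, greedy
#' linearization into contigs and a second, contig-level round yielding the
#' final blocks (scaffolds).  Deterministic given its inputs.
#'
#' @param genomes named list of `genome` objects (extant species).
#' @param forest list of reconciled `gene_tree`.
#' @param stree a `species_tree`.
#' @param ancestor internal species-tree node to reconstruct.
#' @param round1_only if `TRUE`, stop after the first linearization round.
#' @return object of class `ancestral_genome`: list with `ancestor`, `blocks`
#'   (named list `block_1`, `block_2`, ... of data.frames `gene`, `orient`,
#'   numbered by decreasing gene count then first gene id), `content`
#'   (the [ancestral_gene_content()] result) and `stats` (per-stage counts).
#' @export
reconstruct_ancestor <- function(genomes, forest, stree, ancestor,
                                 round1_only = FALSE) {
  content <- ancestral_gene_content(forest, stree, ancestor)
  pairs <- informative_pairs(stree, ancestor)
  pairs <- pairs[pairs$a %in% names(genomes) & pairs$b %in% names(genomes), ,
                 drop = FALSE]
  if (nrow(pairs) < 1L)
    validation_error("uninformative ancestor: no informative species pair for '%s'",
                     ancestor)
  involved <- sort(unique(c(pairs$a, pairs$b)))
  projections <- lapply(genomes[involved], project_genome, mapping = content$mapping)
  adj <- list()
  for (i in seq_len(nrow(pairs))) {
    key <- paste(pairs$a[i], pairs$b[i], sep = "~")
    adj[[key]] <- conserved_adjacencies(projections[[pairs$a[i]]],
                                        projections[[pairs$b[i]]])
  }
  graph <- build_adjacency_graph(adj, nodes = content$genes$id)
  contigs <- linearize_greedy(graph)
  blocks <- if (round1_only) contigs else
    scaffold_round2(contigs, projections, pairs)
  names(blocks) <- sprintf("block_%d", seq_along(blocks))
  structure(list(
    ancestor = ancestor, blocks = blocks, content = content,
    stats = list(n_content = nrow(content$genes), n_pairs = nrow(pairs),
                 n_edges = nrow(graph$edges), n_contigs = length(contigs),
                 n_blocks = length(blocks))
  ), class = "ancestral_genome")
}

#' @export
print.ancestral_genome <- function(x, ...) {
  sizes <- vapply(x$blocks, nrow, integer(1))
  cat(sprintf("Ancestral genome of %s: %d genes in %d blocks (largest: %d)\n",
              x$ancestor, sum(sizes), length(sizes),
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' Write ancestral blocks as TSV
#'
#' Columns: ancestor, block_id, rank (1-based within block),
#' ancestral_gene_id, orientation.
#'
#' @param ag an `ancestral_genome`.
#' @param path output file.
#' @param header_comment optional comment lines (written with leading `#`).
#' @export
write_blocks_tsv <- function(ag, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  writeLines("ancestor\tblock_id\trank\tancestral_gene_id\torientation", con)
  for (bid in names(ag$blocks)) {
    b <- ag$blocks[[bid]]
    writeLines(sprintf("%s\t%s\t%d\t%s\t%s", ag$ancestor, bid,
                       seq_len(nrow(b)), b$gene, b$orient), con)
  }
  invisible(path)
}

#' Adjacency key set realised by an ancestral genome's blocks
#'
#' @param ag an `ancestral_genome` (or plain list of block data.frames).
#' @param relabel optional named vector renaming gene ids (e.g. ancestral id
#'   -> family id) before key construction.
#' @return character vector of canonical adjacency keys.
#' @export
ancestral_adjacency_set <- function(ag, relabel = NULL) {
  blocks <- if (inherits(ag, "ancestral_genome")) ag$blocks else ag
  keys <- character()
  for (b in blocks) {
    lab <- if (is.null(relabel)) b$gene else unname(relabel[b$gene])
    keys <- c(keys, adjacency_keys_from_sequence(lab, b$orient))
  }
  unique(keys)
}

#' Precision and recall of a reconstructed adjacency set against a truth set
#' @param reconstructed,truth character vectors of canonical adjacency keys.
#' @return named numeric vector with `precision`, `recall`, `n_true`, `n_rec`.
#' @export
adjacency_precision_recall <- function(reconstructed, truth) {
  tp <- length(intersect(reconstructed, truth))
  c(precision = if (length(reconstructed)) tp / length(reconstructed) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_,
    n_true = length(truth), n_rec = length(reconstructed))
}
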