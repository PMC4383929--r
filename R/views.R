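# Pairwise-comparison backends: homologous gene pairs from the forest,
# dotplot data (ortholog or paralog mode), karyotype painting and marker
# lookup.  Positions are gene RANKS: 1-based indices in the coordinate-sorted
# gene order of each chromosome (for an ancestral genome, the position within
# each block).

#' Rank table of a genome or ancestral genome
#'
#' @param x a `genome` or `ancestral_genome`.
#' @return data.frame `gene`, `chrom`, `rank` (1-based within chromosome).
#' @export
rank_table <- function(x) UseMethod("rank_table")

#' @export
rank_table.genome <- function(x) {
  g <- x$genes
  rank <- stats::ave(seq_len(nrow(g)), g$chromosome, FUN = seq_along)
  data.frame(gene = g$gene_id, chrom = g$chromosome, rank = rank,
             stringsAsFactors = FALSE)
}

#' @export
rank_table.ancestral_genome <- function(x) {
  do.call(rbind, lapply(names(x$blocks), function(bid) {
    b <- x$blocks[[bid]]
    data.frame(gene = b$gene, chrom = bid, rank = seq_len(nrow(b)),
               stringsAsFactors = FALSE)
  }))
}

gt_root_path_idx <- function(tree, i) {
  path <- integer()
  while (!is.na(i)) { path <- c(path, i); i <- tree$nodes[[i]]$parent }
  path
}

#' Homologous gene pairs between two genomes
#'
#' Ortholog mode returns extant gene pairs whose gene-tree LCA is a
#' speciation node; paralog mode (typically a self-comparison) returns pairs
#' whose LCA is a duplication; descent mode pairs each ancestral gene of an
#' ancestor with its extant descendants in the other species.
#'
#' @param forest list of reconciled `gene_tree`.
#' @param stree a `species_tree`.
#' @param species_a,species_b species names; for `mode = "descent"` exactly
#'   one must be an internal (ancestral) node.
#' @param mode one of `"ortholog"`, `"paralog"`, `"descent"`.
#' @return data.frame `gene_a`, `gene_b`.
#' @export
homologous_pairs <- function(forest, stree, species_a, species_b,
                             mode = c("ortholog", "paralog", "descent")) {
  mode <- match.arg(mode)
  if (mode == "descent") {
    anc_is_a <- species_a %in% stree$internal
    anc_is_b <- species_b %in% stree$internal
    if (!xor(anc_is_a, anc_is_b))
      usage_error("descent mode needs exactly one ancestral species (got %s, %s)",
                  species_a, species_b)
    ancestor <- if (anc_is_a) species_a else species_b
    extant <- if (anc_is_a) species_b else species_a
    content <- ancestral_gene_content(forest, stree, ancestor)
    rows <- lapply(names(content$descendants), function(aid) {
      d <- content$descendants[[aid]]
      d <- d[d$species == extant, , drop = FALSE]
      if (!nrow(d)) return(NULL)
      if (anc_is_a) data.frame(gene_a = aid, gene_b = d$gene_id,
                               stringsAsFactors = FALSE)
      else data.frame(gene_a = d$gene_id, gene_b = aid, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    return(if (length(rows)) do.call(rbind, rows) else
      data.frame(gene_a = character(), gene_b = character()))
  }
  want_event <- if (mode == "ortholog") "speciation" else "duplication"
  ga <- character(); gb <- character()
  for (tree in forest) {
    if (gt_needs_reconciliation(tree)) tree <- reconcile_lca(tree, stree)
    leaves <- gt_leaves(tree)
    sp <- vapply(leaves, function(i) tree$nodes[[i]]$species, character(1))
    la <- leaves[sp == species_a]
    lb <- leaves[sp == species_b]
    if (!length(la) || !length(lb)) next
    paths <- lapply(leaves, gt_root_path_idx, tree = tree)
    names(paths) <- as.character(leaves)
    seen <- character()
    for (i in la) for (j in lb) {
      if (i == j) next
      key <- paste(sort(c(i, j)), collapse = "_")
      if (species_a == species_b) {
        if (key %in% seen) next
        seen <- c(seen, key)
      }
      lca <- intersect(paths[[as.character(i)]], paths[[as.character(j)]])[1L]
      if (identical(tree$nodes[[lca]]$event, want_event)) {
        ga <- c(ga, tree$nodes[[i]]$label)
        gb <- c(gb, tree$nodes[[j]]$label)
      }
    }
  }
  data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
}

lookup_rank <- function(rt, genes, who) {
  idx <- match(genes, rt$gene)
  if (anyNA(idx))
    validation_error("gene '%s' absent from genome %s", genes[is.na(idx)][1L], who)
  rt[idx, , drop = FALSE]
}

#' Dotplot data for a pairwise genome comparison
#'
#' @param genome_a,genome_b `genome` or `ancestral_genome` objects.
#' @param pairs data.frame `gene_a`, `gene_b` (see [homologous_pairs()]).
#' @return object of class `dotplot_data`: list with `overview` (matrix of
#'   pair counts, chromosomes of genome A x chromosomes of genome B) and
#'   `points` (data.frame `chrom_a`, `chrom_b`, `rank_a`, `rank_b`, `gene_a`,
#'   `gene_b`, sorted by rank pair within cells).
#' @export
matrix_view <- function(genome_a, genome_b, pairs) {
  rta <- rank_table(genome_a)
  rtb <- rank_table(genome_b)
  chroms_a <- unique(rta$chrom); chroms_b <- unique(rtb$chrom)
  overview <- matrix(0L, length(chroms_a), length(chroms_b),
                     dimnames = list(chroms_a, chroms_b))
  if (nrow(pairs)) {
    pa <- lookup_rank(rta, pairs$gene_a, "A")
    pb <- lookup_rank(rtb, pairs$gene_b, "B")
    points <- data.frame(chrom_a = pa$chrom, chrom_b = pb$chrom,
                         rank_a = pa$rank, rank_b = pb$rank,
                         gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                         stringsAsFactors = FALSE)
    points <- points[order(points$chrom_a, points$chrom_b, points$rank_a,
                           points$rank_b, method = "radix"), , drop = FALSE]
    rownames(points) <- NULL
    tab <- table(factor(points$chrom_a, chroms_a), factor(points$chrom_b, chroms_b))
    overview[] <- as.integer(tab)
  } else {
    points <- data.frame(chrom_a = character(), chrom_b = character(),
                         rank_a = integer(), rank_b = integer(),
                         gene_a = character(), gene_b = character())
  }
  structure(list(overview = overview, points = points), class = "dotplot_data")
}

#' @export
print.dotplot_data <- function(x, ...) {
  cat(sprintf("Dotplot: %d points over %d x %d chromosomes\n",
              nrow(x$points), nrow(x$overview), ncol(x$overview)))
  invisible(x)
}

#' Karyotype painting of one genome by the chromosomes of another
#'
#' Each gene of genome A is coloured by its partner's chromosome in genome B;
#' genes with zero or more than one partner chromosome are `"unassigned"`.
#' An optional odd-window majority filter smooths assigned colours; runs of
#' unassigned genes are absorbed when both flanking segments agree.
#'
#' @param genome_a,genome_b `genome` or `ancestral_genome` objects.
#' @param pairs data.frame `gene_a`, `gene_b`.
#' @param smoothing_window odd window size for majority smoothing (1 = none).
#' @return object of class `karyo_data`: named list (chromosome of A) of
#'   data.frames `start_rank`, `end_rank`, `color`; segments partition each
#'   chromosome and adjacent segments differ in colour.
#' @export
karyo_view <- function(genome_a, genome_b, pairs, smoothing_window = 1) {
  if (smoothing_window %% 2 == 0)
    usage_error("smoothing window must be odd, got %d", smoothing_window)
  rta <- rank_table(genome_a)
  rtb <- rank_table(genome_b)
  partner_chrom <- character()
  if (nrow(pairs)) {
    lookup_rank(rta, pairs$gene_a, "A")  # absence check
    partner_chrom <- rtb$chrom[match(pairs$gene_b, rtb$gene)]
    if (anyNA(partner_chrom))
      validation_error("gene '%s' absent from genome B",
                       pairs$gene_b[is.na(partner_chrom)][1L])
  }
  out <- list()
  for (chrom in unique(rta$chrom)) {
    genes <- rta$gene[rta$chrom == chrom]
    colors <- vapply(genes, function(g) {
      pc <- unique(partner_chrom[pairs$gene_a == g])
      if (length(pc) != 1L) "unassigned" else pc
    }, character(1))
    if (smoothing_window > 1L) colors <- majority_smooth(colors, smoothing_window)
    colors <- absorb_unassigned(colors)
    r <- rle(colors)
    ends <- cumsum(r$lengths)
    out[[chrom]] <- data.frame(start_rank = ends - r$lengths + 1L,
                               end_rank = ends, color = r$values,
                               stringsAsFactors = FALSE)
  }
  structure(out, class = "karyo_data")
}

majority_smooth <- function(colors, w) {
  half <- (w - 1L) %/% 2L
  n <- length(colors)
  out <- colors
  for (i in seq_len(n)) {
    win <- colors[max(1L, i - half):min(n, i + half)]
    win <- win[win != "unassigned"]
    if (!length(win)) next
    tab <- sort(table(win), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) next  # tie: keep original
    out[i] <- names(tab)[1L]
  }
  out
}

absorb_unassigned <- function(colors) {
  r <- rle(colors)
  v <- r$values
  for (k in seq_along(v)) {
    if (v[k] != "unassigned") next
    if (k > 1L && k < length(v) && v[k - 1L] == v[k + 1L]) v[k] <- v[k - 1L]
  }
  inverse.rle(structure(list(lengths = r$lengths, values = v), class = "rle"))
}

#' Locate marker genes of genome B in genome A
#'
#' @param names character vector of genome-B gene names.
#' @param pairs data.frame `gene_a`, `gene_b` mapping genome B to genome A
#'   (`gene_b` = genome-B gene).
#' @param genome_a `genome` or `ancestral_genome`.
#' @return list with `found` (data.frame `name`, `chrom`, `rank`; one row per
#'   partner, so duplicated markers yield several rows) and `not_found`
#'   (character vector); unresolvable names are never an error.
#' @export
locate_markers <- function(names, pairs, genome_a) {
  rta <- rank_table(genome_a)
  found <- list(); missing <- character()
  for (nm in names) {
    partners <- unique(pairs$gene_a[pairs$gene_b == nm])
    partners <- partners[partners %in% rta$gene]
    if (!length(partners)) { missing <- c(missing, nm); next }
    idx <- match(partners, rta$gene)
    found[[length(found) + 1L]] <- data.frame(
      name = nm, chrom = rta$chrom[idx], rank = rta$rank[idx],
      stringsAsFactors = FALSE)
  }
  list(found = if (length(found)) do.call(rbind, found) else
         data.frame(name = character(), chrom = character(), rank = integer()),
       not_found = missing)
}

#' Write dotplot or painting data as JSON
#' @param x a `dotplot_data` or `karyo_data` object.
#' @param path output file.
#' @param meta optional named list recorded under `"meta"`.
#' @export
write_view_json <- function(x, path, meta = NULL) {
  payload <- if (inherits(x, "dotplot_data")) {
    list(type = "dotplot",
         overview = list(chroms_a = rownames(x$overview),
                         chroms_b = colnames(x$overview),
                         counts = unname(apply(x$overview, 1L, as.integer,
                                               simplify = FALSE))),
         points = x$points)
  } else {
    list(type = "karyotype_painting", segments = unclass(x))
  }
  if (!is.null(meta)) payload$meta <- meta
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
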