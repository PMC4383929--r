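# Signed adjacencies and the weighted adjacency graph.  An adjacency joins a
# side (head/tail) of one gene to a side of another; reading a chromosome
# left to right, a "+" gene exposes its tail on the left and its head on the
# right.  An adjacency and its mirror are one object: keys are canonicalized
# with the lexicographically smaller gene id first.

other_side <- function(s) ifelse(s == "head", "tail", "head")

#' Canonical key of a signed adjacency
#'
#' @param g1,g2 gene identifiers.
#' @param s1,s2 sides (`"head"`/`"tail"`) of g1 and g2 that touch.
#' @return canonical key string `"a|sa|b|sb"` with `a < b`, or `NA` for a
#'   self-adjacency.
#' @export
adjacency_key <- function(g1, s1, g2, s2) {
  ifelse(g1 == g2, NA_character_,
         ifelse(g1 < g2, paste(g1, s1, g2, s2, sep = "|"),
                paste(g2, s2, g1, s1, sep = "|")))
}

# Decode keys into a data.frame a/sa/b/sb.
adjacency_decode <- function(keys) {
  if (!length(keys))
    return(data.frame(a = character(), sa = character(), b = character(),
                      sb = character(), key = character(), stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  data.frame(a = f[, 1L], sa = f[, 2L], b = f[, 3L], sb = f[, 4L], key = keys,
             stringsAsFactors = FALSE)
}

# Canonical keys of the consecutive signed pairs of one oriented sequence.
adjacency_keys_from_sequence <- function(labels, orients) {
  n <- length(labels)
  if (n < 2L) return(character())
  g1 <- labels[-n]; g2 <- labels[-1L]
  s1 <- ifelse(orients[-n] == "+", "head", "tail")   # right side of the left gene
  s2 <- ifelse(orients[-1L] == "+", "tail", "head")  # left side of the right gene
  keys <- adjacency_key(g1, s1, g2, s2)
  keys[!is.na(keys)]
}

#' Project an extant genome onto an ancestral gene content
#'
#' Replaces each extant gene having an ancestral image by
#' `(ancestral id, orientation = extant strand)` and drops the rest,
#' preserving chromosome order.
#'
#' @param genome a `genome`.
#' @param mapping named character vector extant gene id -> ancestral id (the
#'   `mapping` component of [ancestral_gene_content()]).
#' @return object of class `projected_genome`: named list of data.frames
#'   (`gene`, `orient`) per chromosome, empty chromosomes dropped.
#' @export
project_genome <- function(genome, mapping) {
  out <- list()
  for (chrom in genome$chromosomes) {
    g <- genome_chromosome(genome, chrom)
    keep <- g$gene_id %in% names(mapping)
    if (!any(keep)) next
    out[[chrom]] <- data.frame(gene = unname(mapping[g$gene_id[keep]]),
                               orient = g$strand[keep], stringsAsFactors = FALSE)
  }
  structure(out, class = "projected_genome")
}

# Adjacency key set realised by one projected genome.  Genes occurring more
# than once in the projection are ambiguous copies and are excluded as
# adjacency endpoints in that genome.
projection_adjacency_set <- function(proj) {
  genes <- unlist(lapply(proj, `[[`, "gene"), use.names = FALSE)
  multi <- unique(genes[duplicated(genes)])
  keys <- character()
  for (chrom in proj) {
    n <- nrow(chrom)
    if (n < 2L) next
    ok <- !(chrom$gene %in% multi)
    pair_ok <- ok[-n] & ok[-1L]
    k <- adjacency_key(chrom$gene[-n],
                       ifelse(chrom$orient[-n] == "+", "head", "tail"),
                       chrom$gene[-1L],
                       ifelse(chrom$orient[-1L] == "+", "tail", "head"))
    keys <- c(keys, k[pair_ok & !is.na(k)])
  }
  unique(keys)
}

#' Adjacencies conserved between two projected genomes
#'
#' An adjacency is conserved when the same two ancestral genes touch with the
#' same pair of sides (after canonicalization) in both projections; a pair
#' conserved as `A+ B+` in one genome and `B- A-` in the other is therefore
#' one adjacency.  Ancestral genes occurring more than once in a projection
#' are skipped as endpoints in that genome.
#'
#' @param proj_x,proj_y `projected_genome` objects over the same content.
#' @return data.frame of conserved adjacencies (`a`, `sa`, `b`, `sb`, `key`).
#' @export
conserved_adjacencies <- function(proj_x, proj_y) {
  keys <- intersect(projection_adjacency_set(proj_x),
                    projection_adjacency_set(proj_y))
  adjacency_decode(sort(keys))
}

#' Combine per-pair adjacency lists into a weighted adjacency graph
#'
#' @param adjacencies named list: species-pair label -> data.frame from
#'   [conserved_adjacencies()] (or character vector of keys).
#' @param nodes character vector of all ancestral gene ids (content).
#' @return object of class `adjacency_graph`: list with `nodes` and `edges`
#'   (data.frame `a`, `sa`, `b`, `sb`, `weight`, `key`); weight = number of
#'   distinct supporting species pairs.
#' @export
build_adjacency_graph <- function(adjacencies, nodes) {
  per_pair <- lapply(adjacencies, function(x) {
    unique(if (is.data.frame(x)) x$key else as.character(x))
  })
  all_keys <- unlist(per_pair, use.names = FALSE)
  if (length(all_keys)) {
    tab <- table(all_keys)
    edges <- adjacency_decode(names(tab))
    edges$weight <- as.integer(tab)
  } else {
    edges <- adjacency_decode(character())
    edges$weight <- integer()
  }
  edges <- edges[order(edges$key, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(nodes)), edges = edges),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("Adjacency graph: %d genes, %d weighted edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}
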