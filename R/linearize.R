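# Greedy linearization of the adjacency graph into contigs: edges are taken
# by decreasing weight (ties broken on the canonical edge key) and accepted
# when both gene sides are still free and acceptance does not close a cycle.
# Accepted edges induce simple paths; every content gene ends up in exactly
# one contig.

#' Linearize an adjacency graph into contigs
#'
#' Edges are visited in order (weight descending, then canonical key
#' ascending); an edge is accepted iff both incident gene sides are free and
#' it does not close a cycle (union-find over genes).  Isolated genes become
#' singleton contigs.  Each contig is read starting from its
#' lexicographically smallest terminal gene; a gene is `+` when its head
#' points in reading direction.
#'
#' @param graph an `adjacency_graph`.
#' @return list of contigs, each a data.frame (`gene`, `orient`), sorted by
#'   decreasing gene count then first gene id.
#' @export
linearize_greedy <- function(graph) {
  edges <- graph$edges
  if (nrow(edges))
    edges <- edges[order(-edges$weight, edges$key, method = "radix"), , drop = FALSE]
  # union-find over genes
  parent <- new.env(parent = emptyenv())
  uf_find <- function(x) {
    r <- x
    while (!is.null(parent[[r]])) r <- parent[[r]]
    r
  }
  occupied <- new.env(parent = emptyenv())  # "gene|side" -> c(gene, side)
  accepted <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges$a[i]; sa <- edges$sa[i]; b <- edges$b[i]; sb <- edges$sb[i]
    ka <- paste0(a, "|", sa); kb <- paste0(b, "|", sb)
    if (!is.null(occupied[[ka]]) || !is.null(occupied[[kb]])) next
    ra <- uf_find(a); rb <- uf_find(b)
    if (ra == rb) next  # would close a cycle
    parent[[ra]] <- rb
    occupied[[ka]] <- c(b, sb)
    occupied[[kb]] <- c(a, sa)
    accepted[[length(accepted) + 1L]] <- c(a, sa, b, sb)
  }
  contigs_from_sides(graph$nodes, occupied)
}

# Reconstruct simple paths from the side-occupancy map.
contigs_from_sides <- function(nodes, occupied) {
  side_of <- function(g, s) occupied[[paste0(g, "|", s)]]
  degree <- vapply(nodes, function(g)
    sum(!is.null(side_of(g, "head")), !is.null(side_of(g, "tail"))), integer(1))
  terminals <- nodes[degree <= 1L]
  visited <- new.env(parent = emptyenv())
  contigs <- list()
  for (start in sort(terminals)) {
    if (!is.null(visited[[start]])) next
    # entry side of the start gene = its free side (tail preferred so that an
    # isolated or tail-free gene reads "+")
    entry <- if (is.null(side_of(start, "tail"))) "tail" else "head"
    genes <- character(); orients <- character()
    g <- start; es <- entry
    repeat {
      visited[[g]] <- TRUE
      genes <- c(genes, g)
      orients <- c(orients, if (es == "tail") "+" else "-")
      nxt <- side_of(g, other_side(es))
      if (is.null(nxt)) break
      g <- nxt[1L]; es <- nxt[2L]
    }
    contigs[[length(contigs) + 1L]] <- data.frame(gene = genes, orient = orients,
                                                  stringsAsFactors = FALSE)
  }
  sort_contigs(contigs)
}

sort_contigs <- function(contigs) {
  if (!length(contigs)) return(contigs)
  len <- vapply(contigs, nrow, integer(1))
  first <- vapply(contigs, function(cg) cg$gene[1L], character(1))
  contigs[order(-len, first, method = "radix")]
}
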