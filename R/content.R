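# Ancestral gene content: one ancestral gene per gene-tree node mapped to the
# ancestor, plus one per tree edge whose species path crosses the ancestor
# strictly.  Also: the informative species pairs of an ancestor (extant pairs
# whose evolutionary path includes it).

#' Infer the ancestral gene content of one ancestor
#'
#' For every reconciled gene tree, an ancestral gene is created for each tree
#' node assigned to `ancestor` and for each tree edge (u,v) such that
#' `ancestor` lies strictly between the species assignments of u and v.  A
#' chain of nodes at the same ancestor (nested duplications) contributes one
#' ancestral gene: the highest node, representing the pre-duplication state;
#' copies exist strictly below.  Each extant gene maps to at most one
#' ancestral gene of the ancestor.
#'
#' @param forest list of reconciled `gene_tree` (see [reconcile_lca()]);
#'   trees still lacking assignments are reconciled on the fly.
#' @param stree a `species_tree`.
#' @param ancestor name of an internal species-tree node.
#' @return list with components:
#'   \describe{
#'     \item{genes}{data.frame: `id`, `family_id`, `kind` (node/edge).}
#'     \item{descendants}{named list (by ancestral id) of data.frames with
#'       `species`, `gene_id` of extant descendants.}
#'     \item{mapping}{named character vector: extant gene id -> ancestral id.}
#'   }
#' @export
ancestral_gene_content <- function(forest, stree, ancestor) {
  st_check_node(stree, ancestor)
  if (!ancestor %in% stree$internal)
    validation_error("'%s' is not an internal node of the species tree", ancestor)
  ids <- character(); fams <- character(); kinds <- character()
  descendants <- list()
  mapping <- character()
  for (tree in forest) {
    if (gt_needs_reconciliation(tree)) tree <- reconcile_lca(tree, stree)
    sp <- vapply(tree$nodes, function(n) n$species, character(1))
    strictly_between <- function(u, v) {
      # proper descendant of sp(u) and proper ancestor of sp(v)
      sp[u] != ancestor && sp[v] != ancestor &&
        st_is_ancestor(stree, sp[u], ancestor) &&
        st_is_ancestor(stree, ancestor, sp[v])
    }
    entry_key <- character()   # "n<i>" / "e<i>" -> ancestral id
    k <- 0L
    for (i in seq_along(tree$nodes)) {
      node <- tree$nodes[[i]]
      # a node at the ancestor counts only when it is the highest node of its
      # root path there: a duplication contributes its pre-duplication state
      # once, the copies exist strictly below
      p_i <- node$parent
      top_at_ancestor <- length(node$children) > 0L && sp[i] == ancestor &&
        (is.na(p_i) || sp[p_i] != ancestor)
      if (top_at_ancestor) {
        k <- k + 1L
        aid <- sprintf("%s.%d", tree$id, k)
        entry_key[[paste0("n", i)]] <- aid
        ids <- c(ids, aid); fams <- c(fams, tree$id); kinds <- c(kinds, "node")
        descendants[[aid]] <- gt_leaf_table(tree, i)
      }
      p <- tree$nodes[[i]]$parent
      if (!is.na(p) && strictly_between(p, i)) {
        k <- k + 1L
        aid <- sprintf("%s.%d", tree$id, k)
        entry_key[[paste0("e", i)]] <- aid
        ids <- c(ids, aid); fams <- c(fams, tree$id); kinds <- c(kinds, "edge")
        descendants[[aid]] <- gt_leaf_table(tree, i)
      }
    }
    if (k == 0L) next
    # extant -> ancestral: the unique node-or-edge at the ancestor on the
    # root path (node entries exist only for the highest node at the ancestor)
    for (lf in gt_leaves(tree)) {
      i <- lf
      repeat {
        if (paste0("n", i) %in% names(entry_key)) {
          mapping[[tree$nodes[[lf]]$label]] <- entry_key[[paste0("n", i)]]
          break
        }
        if (paste0("e", i) %in% names(entry_key)) {
          mapping[[tree$nodes[[lf]]$label]] <- entry_key[[paste0("e", i)]]
          break
        }
        i <- tree$nodes[[i]]$parent
        if (is.na(i)) break
      }
    }
  }
  list(genes = data.frame(id = ids, family_id = fams, kind = kinds,
                          stringsAsFactors = FALSE),
       descendants = descendants,
       mapping = mapping)
}

gt_leaf_table <- function(tree, i) {
  leaves <- integer()
  rec <- function(j) {
    if (length(tree$nodes[[j]]$children) == 0L) leaves <<- c(leaves, j)
    else for (k in tree$nodes[[j]]$children) rec(k)
  }
  rec(i)
  data.frame(species = vapply(leaves, function(j) tree$nodes[[j]]$species, character(1)),
             gene_id = vapply(leaves, function(j) tree$nodes[[j]]$label, character(1)),
             stringsAsFactors = FALSE)
}

#' Informative extant species pairs of an ancestor
#'
#' A pair \{x, y\} is informative for an ancestor when the ancestor lies on
#' the tree path x -> LCA(x,y) -> y; the pairwise comparison of x and y then
#' carries signal about the ancestor's gene order.
#'
#' @param stree a `species_tree`.
#' @param ancestor internal node name.
#' @return data.frame with columns `a`, `b` (a < b lexicographically).
#' @export
informative_pairs <- function(stree, ancestor) {
  st_check_node(stree, ancestor)
  if (!ancestor %in% stree$internal)
    validation_error("'%s' is not an internal node of the species tree", ancestor)
  leaves <- stree$leaves
  paths <- lapply(leaves, st_root_path, stree = stree)
  names(paths) <- leaves
  a <- character(); b <- character()
  if (length(leaves) >= 2L) {
    for (i in seq_len(length(leaves) - 1L)) for (j in seq.int(i + 1L, length(leaves))) {
      x <- leaves[i]; y <- leaves[j]
      lca <- intersect(paths[[x]], paths[[y]])[1L]
      px <- paths[[x]][seq_len(match(lca, paths[[x]]))]
      py <- paths[[y]][seq_len(match(lca, paths[[y]]))]
      if (ancestor %in% union(px, py)) { a <- c(a, x); b <- c(b, y) }
    }
  }
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}
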