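# LCA (most-parsimonious) reconciliation of gene trees against the species
# tree: every internal node is mapped to the last common ancestor of its
# children's mappings, and labelled a duplication exactly when its mapping
# equals the mapping of at least one child.

#' Reconcile a gene tree with the species tree by LCA mapping
#'
#' Internal nodes lacking a species assignment receive the LCA of their
#' children's assignments; nodes lacking an event label are labelled
#' `duplication` iff their assignment equals the assignment of at least one
#' child, else `speciation`.  Assignments already present (e.g. from NHX
#' input) are kept, but must be ancestral-or-equal to every child's
#' assignment; violations raise a validation error naming the node.
#'
#' @param tree a `gene_tree` (possibly partially annotated).
#' @param stree a `species_tree`.
#' @return the fully annotated `gene_tree`.
#' @export
reconcile_lca <- function(tree, stree) {
  tree <- resolve_leaf_species(tree, stree)
  for (i in gt_postorder(tree)) {
    node <- tree$nodes[[i]]
    if (length(node$children) == 0L) next
    kid_sp <- vapply(node$children, function(k) tree$nodes[[k]]$species, character(1))
    lca <- st_lca(stree, kid_sp)
    if (is.null(node$species)) {
      tree$nodes[[i]]$species <- lca
    } else {
      st_check_node(stree, node$species)
      ok <- all(vapply(kid_sp, function(s) st_is_ancestor(stree, node$species, s),
                       logical(1)))
      if (!ok)
        validation_error(
          "node '%s' of %s assigned to '%s', not ancestral to children (%s)",
          if (nzchar(node$label %||% "")) node$label else sprintf("#%d", i),
          tree$id, node$species, paste(kid_sp, collapse = ", "))
    }
    if (is.null(node$event)) {
      dup <- any(kid_sp == tree$nodes[[i]]$species)
      tree$nodes[[i]]$event <- if (dup) "duplication" else "speciation"
    }
  }
  tree
}

#' Reconcile every tree of a forest
#' @param forest list of `gene_tree`.
#' @param stree a `species_tree`.
#' @export
reconcile_forest <- function(forest, stree) {
  lapply(forest, reconcile_lca, stree = stree)
}
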