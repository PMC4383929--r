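# Species tree: a rooted tree with uniquely named leaves (extant species) and
# internal nodes (ancestors).  Stored as flat parent/children tables keyed by
# node name so that ancestor paths and LCA queries are cheap.

#' Construct a species tree from parent/child relations
#'
#' @param parent named character vector: `parent[node]` is the parent's name;
#'   the root has `NA`.
#' @param auto_named character vector of node names that were generated rather
#'   than read from input.
#' @return an object of class `species_tree` with components `nodes`, `parent`,
#'   `children`, `root`, `leaves`, `internal`, `auto_named`.
#' @keywords internal
new_species_tree <- function(parent, auto_named = character()) {
  nodes <- names(parent)
  if (anyDuplicated(nodes))
    validation_error("duplicate node names in species tree: %s",
                     paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  root <- nodes[is.na(parent)]
  if (length(root) != 1L)
    validation_error("species tree must have exactly one root, found %d", length(root))
  children <- split(nodes[!is.na(parent)], parent[!is.na(parent)])
  children <- lapply(children, sort)
  leaves <- sort(setdiff(nodes, names(children)))
  if (length(leaves) < 2L)
    validation_error("species tree needs at least 2 leaves, found %d", length(leaves))
  structure(list(
    nodes = nodes, parent = parent, children = children, root = root,
    leaves = leaves, internal = setdiff(nodes, leaves), auto_named = auto_named
  ), class = "species_tree")
}

#' Read a rooted species tree from a newick file
#'
#' Internal nodes without labels are auto-named deterministically by joining
#' the sorted names of the leaves below them with `_`, and recorded in the
#' tree's `auto_named` field.
#'
#' @param path path to a newick file (or a newick string containing `;`).
#' @return a `species_tree`.
#' @export
read_species_tree <- function(path) {
  txt <- if (grepl(";", path, fixed = TRUE)) path else
    paste(readLines(path, warn = FALSE), collapse = "")
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) parse_error("unparseable newick: %s", substr(txt, 1, 60))
  if (ape::Ntip(phy) < 2L)
    validation_error("species tree needs at least 2 leaves")
  species_tree_from_phylo(phy)
}

# Convert an ape phylo into a species_tree, auto-naming unlabeled internals.
species_tree_from_phylo <- function(phy) {
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  labels <- character(ntip + nnode)
  labels[seq_len(ntip)] <- phy$tip.label
  inode_labels <- phy$node.label %||% rep("", nnode)
  if (length(inode_labels) < nnode) inode_labels <- c(inode_labels, rep("", nnode))
  auto <- character()
  # leaves below each node, computed bottom-up over edges sorted child-desc
  below <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) below[[i]] <- phy$tip.label[i]
  edge <- phy$edge[order(-phy$edge[, 2L]), , drop = FALSE]
  # process internal nodes from highest index to root; children have larger
  # indices than tips only sometimes, so iterate until all filled
  remaining <- seq.int(ntip + 1L, ntip + nnode)
  while (length(remaining)) {
    progressed <- FALSE
    for (n in remaining) {
      kids <- phy$edge[phy$edge[, 1L] == n, 2L]
      if (all(!vapply(below[kids], is.null, logical(1)))) {
        below[[n]] <- sort(unique(unlist(below[kids])))
        progressed <- TRUE
      }
    }
    remaining <- remaining[vapply(below[remaining], is.null, logical(1))]
    if (!progressed && length(remaining))
      parse_error("malformed tree topology")
  }
  for (j in seq_len(nnode)) {
    lab <- inode_labels[j]
    if (is.na(lab) || lab == "") {
      lab <- paste(below[[ntip + j]], collapse = "_")
      auto <- c(auto, lab)
    }
    labels[ntip + j] <- lab
  }
  parent <- rep(NA_character_, ntip + nnode)
  names(parent) <- labels
  for (k in seq_len(nrow(phy$edge)))
    parent[labels[phy$edge[k, 2L]]] <- labels[phy$edge[k, 1L]]
  new_species_tree(parent, auto_named = auto)
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("Species tree: %d leaves, %d ancestors (root: %s)\n",
              length(x$leaves), length(x$internal), x$root))
  cat("  leaves:", paste(x$leaves, collapse = ", "), "\n")
  invisible(x)
}

#' Write a species tree as newick
#' @param stree a `species_tree`.
#' @param path output file; if `NULL` the newick string is returned.
#' @export
write_species_tree <- function(stree, path = NULL) {
  rec <- function(n) {
    kids <- stree$children[[n]]
    if (is.null(kids)) n
    else paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")", n)
  }
  s <- paste0(rec(stree$root), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

# -- path / ancestry queries -------------------------------------------------

st_check_node <- function(stree, name) {
  if (!name %in% stree$nodes)
    validation_error("node '%s' not in species tree", name)
  invisible(name)
}

#' Path from a node up to the root (inclusive)
#' @param stree a `species_tree`.
#' @param name node name.
#' @return character vector, `name` first, root last.
#' @export
st_root_path <- function(stree, name) {
  st_check_node(stree, name)
  path <- character()
  while (!is.na(name)) {
    path <- c(path, name)
    name <- stree$parent[[name]]
  }
  path
}

#' Is `a` ancestral to or equal to `b`?
#' @param stree a `species_tree`.
#' @param a,b node names.
#' @export
st_is_ancestor <- function(stree, a, b) {
  a %in% st_root_path(stree, b)
}

#' Last common ancestor of a set of nodes
#' @param stree a `species_tree`.
#' @param names character vector of node names.
#' @export
st_lca <- function(stree, names) {
  stopifnot(length(names) >= 1L)
  path <- st_root_path(stree, names[[1L]])
  for (n in names[-1L]) path <- intersect(path, st_root_path(stree, n))
  if (!length(path)) validation_error("no common ancestor")
  path[[1L]]  # intersect preserves order of first path: deepest common first
}

#' Leaves at or below a node
#' @param stree a `species_tree`.
#' @param name node name.
#' @export
st_leaves_below <- function(stree, name) {
  st_check_node(stree, name)
  kids <- stree$children[[name]]
  if (is.null(kids)) return(name)
  sort(unlist(lapply(kids, st_leaves_below, stree = stree), use.names = FALSE))
}
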