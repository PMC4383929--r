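# Reconciled gene trees: rooted trees whose leaves are extant genes and whose
# internal nodes carry a species-tree assignment plus an event label
# (speciation or duplication).  Input is newick with NHX annotations
# ("[&&NHX:S=<species>:D=Y|N]"); assignments missing from the input are filled
# by reconcile_lca().

new_gene_tree <- function(nodes, root, id) {
  structure(list(nodes = nodes, root = root, id = id), class = "gene_tree")
}

gt_is_leaf <- function(tree, i) length(tree$nodes[[i]]$children) == 0L

gt_leaves <- function(tree) {
  which(vapply(tree$nodes, function(n) length(n$children) == 0L, logical(1)))
}

#' @export
print.gene_tree <- function(x, ...) {
  lv <- gt_leaves(x)
  sp <- vapply(x$nodes[lv], function(n) n$species %||% "?", character(1))
  cat(sprintf("Gene tree %s: %d genes in %d species%s\n", x$id, length(lv),
              length(unique(sp)),
              if (gt_needs_reconciliation(x)) " (needs reconciliation)" else ""))
  invisible(x)
}

gt_needs_reconciliation <- function(tree) {
  any(vapply(seq_along(tree$nodes), function(i) {
    n <- tree$nodes[[i]]
    if (length(n$children) == 0L) is.null(n$species)
    else is.null(n$species) || is.null(n$event)
  }, logical(1)))
}

# -- NHX parsing -------------------------------------------------------------

# Recursive-descent parser for one newick/NHX record.  Branch lengths are
# accepted and discarded; only S= and D= tags are interpreted.
parse_nhx <- function(s, id = "tree") {
  s <- trimws(s)
  env <- new.env(parent = emptyenv())
  env$i <- 1L
  env$nodes <- list()
  n <- nchar(s)
  peek <- function() if (env$i > n) "" else substr(s, env$i, env$i)
  advance <- function() env$i <- env$i + 1L

  read_label <- function() {
    start <- env$i
    while (env$i <= n && !substr(s, env$i, env$i) %in% c("(", ")", ",", ":", ";", "["))
      advance()
    substr(s, start, env$i - 1L)
  }
  read_meta <- function() {
    # optional :branch-length then optional [&&NHX:...] comment (either order-tolerant)
    tags <- list()
    repeat {
      ch <- peek()
      if (ch == ":") {
        advance()
        while (env$i <= n && grepl("[0-9eE.+-]", substr(s, env$i, env$i))) advance()
      } else if (ch == "[") {
        close_i <- regexpr("]", substr(s, env$i, n), fixed = TRUE)
        if (close_i < 0) parse_error("unterminated NHX comment in %s", id)
        com <- substr(s, env$i, env$i + close_i - 1L)
        env$i <- env$i + close_i
        body <- sub("^\\[&&NHX:?", "", sub("\\]$", "", com))
        if (nzchar(body)) {
          for (kv in strsplit(body, ":", fixed = TRUE)[[1]]) {
            eq <- regexpr("=", kv, fixed = TRUE)
            if (eq > 0) tags[[substr(kv, 1, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
          }
        }
      } else break
    }
    tags
  }
  add_node <- function(node) {
    env$nodes[[length(env$nodes) + 1L]] <- node
    length(env$nodes)
  }
  subtree <- function() {
    if (peek() == "(") {
      advance()
      kids <- c(subtree())
      while (peek() == ",") { advance(); kids <- c(kids, subtree()) }
      if (peek() != ")") parse_error("expected ')' at position %d in %s", env$i, id)
      advance()
      label <- read_label()
      tags <- read_meta()
      event <- if (!is.null(tags$D)) {
        if (identical(tags$D, "Y")) "duplication" else "speciation"
      } else NULL
      idx <- add_node(list(children = kids, parent = NA_integer_,
                           label = label, species = tags$S, event = event))
      for (k in kids) env$nodes[[k]]$parent <- idx
      idx
    } else {
      label <- read_label()
      if (!nzchar(label)) parse_error("empty leaf label at position %d in %s", env$i, id)
      tags <- read_meta()
      add_node(list(children = integer(), parent = NA_integer_,
                    label = label, species = tags$S, event = NULL))
    }
  }
  root <- subtree()
  if (peek() != ";") parse_error("missing ';' terminator in %s", id)
  new_gene_tree(env$nodes, root, id)
}

#' Read a forest of reconciled gene trees (newick/NHX, one record per line)
#'
#' NHX tags `S=` (species assignment) and `D=Y|N` (duplication flag) are read
#' when present.  Leaf species come from the `S` tag, or, when a species tree
#' is supplied, from the longest `_<species>` suffix of the leaf label.
#' Records lacking internal assignments are accepted and flagged; complete
#' them with [reconcile_lca()].
#'
#' @param path file with one newick/NHX record per line.
#' @param stree optional `species_tree` used to resolve and validate leaf
#'   species; leaves naming unknown species raise a validation error listing
#'   the offenders.
#' @return list of `gene_tree` objects.
#' @export
read_gene_forest <- function(path, stree = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  forest <- lapply(seq_along(lines), function(k)
    parse_nhx(lines[[k]], id = sprintf("tree_%04d", k)))
  if (!is.null(stree)) forest <- lapply(forest, resolve_leaf_species, stree = stree)
  forest
}

# Fill leaf species from label suffixes and validate against the species tree.
resolve_leaf_species <- function(tree, stree) {
  bad <- character()
  for (i in gt_leaves(tree)) {
    node <- tree$nodes[[i]]
    if (is.null(node$species)) {
      hits <- stree$leaves[endsWith(node$label, paste0("_", stree$leaves))]
      if (length(hits)) {
        tree$nodes[[i]]$species <- hits[which.max(nchar(hits))]
      } else bad <- c(bad, node$label)
    } else if (!node$species %in% stree$leaves) {
      bad <- c(bad, sprintf("%s (species %s)", node$label, node$species))
    }
  }
  if (length(bad))
    validation_error("leaf species not in species tree [%s]: %s",
                     tree$id, paste(bad, collapse = ", "))
  tree
}

#' Write a gene forest as newick/NHX, one record per line
#' @param forest list of `gene_tree`.
#' @param path output file; if `NULL`, the lines are returned.
#' @export
write_gene_forest <- function(forest, path = NULL) {
  fmt_node <- function(tree, i) {
    node <- tree$nodes[[i]]
    tags <- character()
    if (!is.null(node$species)) tags <- c(tags, paste0("S=", node$species))
    if (!is.null(node$event))
      tags <- c(tags, paste0("D=", if (node$event == "duplication") "Y" else "N"))
    meta <- if (length(tags)) paste0("[&&NHX:", paste(tags, collapse = ":"), "]") else ""
    if (length(node$children) == 0L) paste0(node$label, meta)
    else paste0("(", paste(vapply(node$children, function(k) fmt_node(tree, k),
                                  character(1)), collapse = ","),
                ")", node$label, meta)
  }
  lines <- vapply(forest, function(tr) paste0(fmt_node(tr, tr$root), ";"), character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

# Post-order traversal indices.
gt_postorder <- function(tree) {
  out <- integer()
  rec <- function(i) {
    for (k in tree$nodes[[i]]$children) rec(k)
    out <<- c(out, i)
  }
  rec(tree$root)
  out
}
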