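# Clade simulator: evolves a root gene order down a species tree under
# inversion / translocation / fusion / fission / (tandem) duplication / loss
# events, recording the TRUE genome at every node, the per-branch event log
# and a reconciled gene forest consistent with the events.  The working
# representation is a named list of chromosomes, each a data.frame
# (gene_id, family_id, orient); coordinates are materialised only when
# genome objects are emitted.

# -- event application (deterministic; parameters fully specified) -----------

apply_event <- function(chroms, ev) {
  switch(ev$type,
    inversion = {
      cg <- chroms[[ev$chrom]]
      seg <- cg[ev$i:ev$j, , drop = FALSE]
      seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
      seg$orient <- flip_orient(seg$orient)
      chroms[[ev$chrom]] <- rbind(
        if (ev$i > 1L) cg[seq_len(ev$i - 1L), , drop = FALSE],
        seg,
        if (ev$j < nrow(cg)) cg[seq.int(ev$j + 1L, nrow(cg)), , drop = FALSE])
      chroms
    },
    translocation = {
      cg <- chroms[[ev$chrom]]
      seg <- cg[ev$i:ev$j, , drop = FALSE]
      rest <- cg[setdiff(seq_len(nrow(cg)), ev$i:ev$j), , drop = FALSE]
      chroms[[ev$chrom]] <- rest
      dst <- chroms[[ev$dst]]
      pos <- ev$pos  # insert after this many genes of dst (post-removal state)
      chroms[[ev$dst]] <- rbind(
        if (pos > 0L) dst[seq_len(pos), , drop = FALSE],
        seg,
        if (pos < nrow(dst)) dst[seq.int(pos + 1L, nrow(dst)), , drop = FALSE])
      chroms
    },
    fusion = {
      chroms[[ev$chrom1]] <- rbind(chroms[[ev$chrom1]], chroms[[ev$chrom2]])
      chroms[[ev$chrom2]] <- NULL
      chroms
    },
    fission = {
      cg <- chroms[[ev$chrom]]
      chroms[[ev$chrom]] <- cg[seq_len(ev$k), , drop = FALSE]
      chroms[[ev$new_name]] <- cg[seq.int(ev$k + 1L, nrow(cg)), , drop = FALSE]
      chroms
    },
    duplication = {
      cg <- chroms[[ev$chrom]]
      copy <- cg[ev$pos, , drop = FALSE]
      copy$gene_id <- ev$new_id
      chroms[[ev$chrom]] <- rbind(
        cg[seq_len(ev$pos), , drop = FALSE], copy,
        if (ev$pos < nrow(cg)) cg[seq.int(ev$pos + 1L, nrow(cg)), , drop = FALSE])
      chroms
    },
    loss = {
      cg <- chroms[[ev$chrom]]
      chroms[[ev$chrom]] <- cg[-ev$pos, , drop = FALSE]
      chroms
    },
    stop("unknown event type: ", ev$type))
}

#' Replay a recorded event log on a chromosome set
#'
#' Events carry fully specified parameters, so replay is deterministic:
#' replaying a branch log on the parent's stored chromosomes reproduces the
#' child's stored chromosomes exactly.
#'
#' @param chroms named list of chromosome data.frames (`gene_id`,
#'   `family_id`, `orient`), as stored in a `simulated_clade`'s `state`.
#' @param events list of event records from the clade's `events` field.
#' @return the evolved chromosome list.
#' @export
replay_events <- function(chroms, events) {
  for (ev in events) chroms <- apply_event(chroms, ev)
  chroms
}

# -- random event drawing ----------------------------------------------------

draw_branch_events <- function(chroms, rates, counter_env, max_per_type) {
  events <- list()
  gene_count <- function() sum(vapply(chroms, nrow, integer(1)))
  pick_gene <- function() {
    sizes <- vapply(chroms, nrow, integer(1))
    total <- sum(sizes)
    if (total == 0L) return(NULL)
    flat <- sample.int(total, 1L)
    ci <- findInterval(flat, cumsum(sizes), left.open = TRUE) + 1L
    pos <- flat - c(0L, cumsum(sizes))[ci]
    list(chrom = names(chroms)[ci], pos = pos)
  }
  for (type in c("inversion", "translocation", "fusion", "fission",
                 "duplication", "loss")) {
    rate <- rates[[type]] %||% 0
    if (rate <= 0) next
    n_ev <- min(stats::rpois(1L, rate), max_per_type)
    for (e in seq_len(n_ev)) {
      ev <- switch(type,
        inversion = {
          elig <- names(chroms)[vapply(chroms, nrow, integer(1)) >= 2L]
          if (!length(elig)) validation_error("impossible inversion: no chromosome with >= 2 genes")
          chrom <- sample(elig, 1L)
          ij <- sort(sample.int(nrow(chroms[[chrom]]), 2L))
          list(type = "inversion", chrom = chrom, i = ij[1L], j = ij[2L])
        },
        translocation = {
          elig <- names(chroms)[vapply(chroms, nrow, integer(1)) >= 1L]
          if (!length(elig)) validation_error("impossible translocation: empty genome")
          chrom <- sample(elig, 1L)
          n <- nrow(chroms[[chrom]])
          i <- sample.int(n, 1L)
          j <- min(n, i + sample.int(5L, 1L) - 1L)
          dst <- sample(names(chroms), 1L)
          n_dst <- nrow(chroms[[dst]]) - if (dst == chrom) (j - i + 1L) else 0L
          pos <- sample.int(n_dst + 1L, 1L) - 1L
          list(type = "translocation", chrom = chrom, i = i, j = j,
               dst = dst, pos = pos)
        },
        fusion = {
          if (length(chroms) < 2L) validation_error("impossible fusion: single chromosome")
          cs <- sample(names(chroms), 2L)
          list(type = "fusion", chrom1 = cs[1L], chrom2 = cs[2L])
        },
        fission = {
          elig <- names(chroms)[vapply(chroms, nrow, integer(1)) >= 2L]
          if (!length(elig)) validation_error("impossible fission: no chromosome with >= 2 genes")
          chrom <- sample(elig, 1L)
          k <- sample.int(nrow(chroms[[chrom]]) - 1L, 1L)
          counter_env$chrom <- counter_env$chrom + 1L
          list(type = "fission", chrom = chrom, k = k,
               new_name = sprintf("chr%d", counter_env$chrom))
        },
        duplication = {
          g <- pick_gene()
          if (is.null(g)) validation_error("impossible duplication: empty genome")
          counter_env$gene <- counter_env$gene + 1L
          src <- chroms[[g$chrom]]$gene_id[g$pos]
          list(type = "duplication", chrom = g$chrom, pos = g$pos,
               src_id = src, new_id = sprintf("G%06d", counter_env$gene))
        },
        loss = {
          if (gene_count() <= 1L) validation_error("impossible loss: last gene")
          g <- pick_gene()
          list(type = "loss", chrom = g$chrom, pos = g$pos,
               gene_id = chroms[[g$chrom]]$gene_id[g$pos])
        })
      chroms <- apply_event(chroms, ev)
      events[[length(events) + 1L]] <- ev
    }
  }
  list(chroms = chroms, events = events)
}

# -- gene-forest construction from the event history -------------------------

# Nested duplication structure of one founder gene across one branch:
# "leaf" nodes carry surviving gene ids, "dup" nodes a left/right pair;
# NULL = lineage lost on the branch.
branch_struct <- function(events, gene_id) {
  contains <- function(t, id) {
    if (is.null(t)) FALSE
    else if (t$kind == "leaf") t$id == id
    else contains(t$l, id) || contains(t$r, id)
  }
  replace_leaf <- function(t, id, newnode) {
    if (t$kind == "leaf") { if (t$id == id) newnode else t }
    else { t$l <- replace_leaf(t$l, id, newnode); t$r <- replace_leaf(t$r, id, newnode); t }
  }
  prune <- function(t, id) {
    if (is.null(t)) return(NULL)
    if (t$kind == "leaf") return(if (t$id == id) NULL else t)
    t$l <- prune(t$l, id); t$r <- prune(t$r, id)
    if (is.null(t$l)) return(t$r)
    if (is.null(t$r)) return(t$l)
    t
  }
  t <- list(kind = "leaf", id = gene_id)
  for (ev in events) {
    if (ev$type == "duplication" && contains(t, ev$src_id)) {
      t <- replace_leaf(t, ev$src_id,
                        list(kind = "dup", l = list(kind = "leaf", id = ev$src_id),
                             r = list(kind = "leaf", id = ev$new_id)))
    } else if (ev$type == "loss" && contains(t, ev$gene_id)) {
      t <- prune(t, ev$gene_id)
    }
  }
  t
}

# Grow the gene tree of one founder below a species node; returns a nested
# node list (species/event/children or extant gene) or NULL if extinct.
grow_gene_tree <- function(gene_id, node, stree, branch_events) {
  kids <- stree$children[[node]]
  if (is.null(kids))
    return(list(extant = TRUE, gene = gene_id, species = node))
  subtrees <- list()
  for (child in kids) {
    bs <- branch_struct(branch_events[[child]], gene_id)
    conv <- function(t) {
      if (is.null(t)) return(NULL)
      if (t$kind == "leaf") return(grow_gene_tree(t$id, child, stree, branch_events))
      l <- conv(t$l); r <- conv(t$r)
      if (is.null(l)) return(r)
      if (is.null(r)) return(l)
      list(extant = FALSE, species = child, event = "duplication",
           children = list(l, r))
    }
    st <- conv(bs)
    if (!is.null(st)) subtrees[[length(subtrees) + 1L]] <- st
  }
  if (!length(subtrees)) return(NULL)
  if (length(subtrees) == 1L) return(subtrees[[1L]])
  list(extant = FALSE, species = node, event = "speciation", children = subtrees)
}

# Flatten a nested gene-tree structure into a gene_tree object; extant leaves
# are labelled "<gene_id>_<species>".
flatten_gene_tree <- function(nested, id) {
  nodes <- list()
  rec <- function(t) {
    if (isTRUE(t$extant)) {
      nodes[[length(nodes) + 1L]] <<- list(
        children = integer(), parent = NA_integer_,
        label = paste0(t$gene, "_", t$species), species = t$species, event = NULL)
      return(length(nodes))
    }
    kid_idx <- vapply(t$children, rec, integer(1))
    # internal assignments are left for reconcile_lca: LCA labels are the
    # ones the forest contract guarantees (a lost duplicate can make the
    # event-log node unrecoverable by parsimony)
    nodes[[length(nodes) + 1L]] <<- list(
      children = kid_idx, parent = NA_integer_, label = "",
      species = NULL, event = NULL)
    idx <- length(nodes)
    for (k in kid_idx) nodes[[k]]$parent <<- idx
    idx
  }
  root <- rec(nested)
  new_gene_tree(nodes, root, id)
}

# -- genome materialisation --------------------------------------------------

chroms_to_genome <- function(chroms, species, extant) {
  parts <- lapply(names(chroms), function(cn) {
    cg <- chroms[[cn]]
    if (!nrow(cg)) return(NULL)
    n <- nrow(cg)
    data.frame(
      gene_id = if (extant) paste0(cg$gene_id, "_", species) else cg$gene_id,
      family_id = cg$family_id, chromosome = cn,
      start = (seq_len(n) - 1L) * 1000, end = (seq_len(n) - 1L) * 1000 + 500,
      strand = cg$orient, stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  new_genome(species, do.call(rbind, parts))
}

#' Simulate the evolution of a gene-ordered clade
#'
#' Starting from a root genome of `n_genes` genes on `n_chromosomes`
#' chromosomes, each branch of the species tree receives a Poisson-distributed
#' number of events per type (capped at `max_events_per_branch`) which are
#' applied in a fixed type order.  True genomes at every node, per-branch
#' event logs and a reconciled gene forest (leaves `<gene>_<species>`, NHX S
#' and D tags) are recorded.
#'
#' @param n_genes number of root genes (ids `G000001`...).
#' @param n_chromosomes number of root chromosomes (`chr1`...).
#' @param stree a `species_tree`.
#' @param rates named list of per-branch event means: `inversion`,
#'   `translocation`, `fusion`, `fission`, `duplication`, `loss` (missing
#'   entries are 0).
#' @param seed integer seed; the whole clade is reproducible from it.
#' @param max_events_per_branch cap on the Poisson draw per type (default 10).
#' @return object of class `simulated_clade`: list with `stree`, `state`
#'   (chromosome lists per node), `genomes` (`genome` objects per node;
#'   extant gene ids are suffixed `_<species>`), `forest` (reconciled
#'   `gene_tree` list), `events` (per child node), `seed`.
#' @export
simulate_clade <- function(n_genes, n_chromosomes, stree, rates = list(),
                           seed, max_events_per_branch = 10L) {
  if (n_genes < n_chromosomes || n_chromosomes < 1L)
    validation_error("need n_genes >= n_chromosomes >= 1")
  if (any(unlist(rates) < 0)) validation_error("rates must be >= 0")
  set.seed(seed)
  ids <- sprintf("G%06d", seq_len(n_genes))
  sizes <- diff(round(seq(0, n_genes, length.out = n_chromosomes + 1L)))
  root_chroms <- list()
  at <- 0L
  for (k in seq_len(n_chromosomes)) {
    idx <- seq.int(at + 1L, at + sizes[k]); at <- at + sizes[k]
    root_chroms[[sprintf("chr%d", k)]] <- data.frame(
      gene_id = ids[idx], family_id = ids[idx],
      orient = sample(c("+", "-"), length(idx), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  counter_env <- new.env(parent = emptyenv())
  counter_env$gene <- n_genes
  counter_env$chrom <- n_chromosomes
  state <- list(); events <- list()
  state[[stree$root]] <- root_chroms
  preorder <- function(node) {
    for (child in stree$children[[node]] %||% character()) {
      res <- draw_branch_events(state[[node]], rates, counter_env,
                                max_events_per_branch)
      state[[child]] <<- res$chroms
      events[[child]] <<- res$events
      preorder(child)
    }
  }
  preorder(stree$root)
  genomes <- lapply(stree$nodes, function(n)
    chroms_to_genome(state[[n]], n, extant = n %in% stree$leaves))
  names(genomes) <- stree$nodes
  forest <- list()
  for (fam in ids) {
    nested <- grow_gene_tree(fam, stree$root, stree, events)
    if (is.null(nested)) next
    forest[[length(forest) + 1L]] <- flatten_gene_tree(nested, fam)
  }
  forest <- reconcile_forest(forest, stree)
  structure(list(stree = stree, state = state, genomes = genomes,
                 forest = forest, events = events, seed = seed),
            class = "simulated_clade")
}

#' @export
print.simulated_clade <- function(x, ...) {
  cat(sprintf("Simulated clade: %d species-tree nodes, %d gene families, seed %d\n",
              length(x$stree$nodes), length(x$forest), x$seed))
  invisible(x)
}

#' Adjacency key set of a stored clade genome
#'
#' @param clade a `simulated_clade`.
#' @param node species-tree node name.
#' @param label `"gene_id"` or `"family_id"` labels for the keys.
#' @return character vector of canonical adjacency keys.
#' @export
clade_adjacency_set <- function(clade, node, label = c("gene_id", "family_id")) {
  label <- match.arg(label)
  keys <- character()
  for (cg in clade$state[[node]]) {
    if (nrow(cg) < 2L) next
    keys <- c(keys, adjacency_keys_from_sequence(cg[[label]], cg$orient))
  }
  unique(keys)
}

#' Write a simulated clade as pipeline input files
#'
#' Writes `genes/<species>.tsv` for every extant species, `species_tree.nwk`
#' and `forest.nhx` under `dir`, in the formats the readers of this package
#' consume.
#'
#' @param clade a `simulated_clade`.
#' @param dir output directory (created if needed).
#' @export
write_clade <- function(clade, dir) {
  dir.create(file.path(dir, "genes"), recursive = TRUE, showWarnings = FALSE)
  for (sp in clade$stree$leaves)
    write_gene_table(clade$genomes[[sp]], file.path(dir, "genes", paste0(sp, ".tsv")))
  write_species_tree(clade$stree, file.path(dir, "species_tree.nwk"))
  write_gene_forest(clade$forest, file.path(dir, "forest.nhx"))
  invisible(dir)
}
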