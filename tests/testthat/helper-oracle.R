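# Independent re-implementation of the greedy linearization rules (explicit
# side scanning + igraph connectivity) and a random-graph generator; used as
# the oracle route against linearize_greedy().

# Independent oracle: same greedy contract, different machinery.
oracle_accepted_edges <- function(graph) {
  edges <- graph$edges
  if (!nrow(edges)) return(character())
  edges <- edges[order(-edges$weight, edges$key, method = "radix"), , drop = FALSE]
  accepted <- edges[0, , drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, , drop = FALSE]
    used <- c(paste0(accepted$a, ".", accepted$sa),
              paste0(accepted$b, ".", accepted$sb))
    if (paste0(e$a, ".", e$sa) %in% used || paste0(e$b, ".", e$sb) %in% used) next
    g <- igraph::graph_from_data_frame(
      accepted[, c("a", "b"), drop = FALSE], directed = FALSE,
      vertices = data.frame(name = graph$nodes))
    comp <- igraph::components(g)$membership
    if (comp[[e$a]] == comp[[e$b]]) next
    accepted <- rbind(accepted, e)
  }
  sort(accepted$key)
}

random_graph <- function(n_nodes, n_edges) {
  nodes <- sprintf("g%02d", seq_len(n_nodes))
  adj <- list()
  for (k in seq_len(n_edges)) {
    gs <- sample(nodes, 2L)
    key <- adjacency_key(gs[1L], sample(c("head", "tail"), 1L),
                         gs[2L], sample(c("head", "tail"), 1L))
    w <- sample.int(4L, 1L)
    for (p in seq_len(w)) {
      pk <- sprintf("pair%d", p)
      adj[[pk]] <- c(adj[[pk]], key)
    }
  }
  build_adjacency_graph(adj, nodes)
}

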