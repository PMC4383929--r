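# Reconciliation, ancestral gene content, informative pairs, projections and
# conserved adjacencies.

forest_from <- function(newick, st) {
  path <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(newick, path)
  read_gene_forest(path, st)
}

test_that("LCA reconciliation assigns species and events", {
  st <- toy_tree()
  f <- forest_from(c("(g1_human,g2_chimp);",
                     "(g1_human,g2_human);",
                     "((g1_human,g1_dog),(g2_human,g2_dog));"), st)
  f <- reconcile_forest(f, st)

  # cherry across species -> speciation at the LCA
  expect_equal(f[[1]]$nodes[[f[[1]]$root]]$species, "Hominidae")
  expect_equal(f[[1]]$nodes[[f[[1]]$root]]$event, "speciation")

  # same-species cherry -> duplication at the species itself
  expect_equal(f[[2]]$nodes[[f[[2]]$root]]$species, "human")
  expect_equal(f[[2]]$nodes[[f[[2]]$root]]$event, "duplication")

  # two parallel human/dog cherries: root duplication at Boreoeutheria,
  # both children speciations at Boreoeutheria
  root <- f[[3]]$root
  expect_equal(f[[3]]$nodes[[root]]$species, "Boreoeutheria")
  expect_equal(f[[3]]$nodes[[root]]$event, "duplication")
  for (k in f[[3]]$nodes[[root]]$children) {
    expect_equal(f[[3]]$nodes[[k]]$species, "Boreoeutheria")
    expect_equal(f[[3]]$nodes[[k]]$event, "speciation")
  }
})

test_that("provided NHX labels are kept but validated", {
  st <- toy_tree()
  # Boreoeutheria is a valid (non-LCA) assignment for a human/chimp cherry
  f <- forest_from("(g1_human,g2_chimp)[&&NHX:S=Boreoeutheria];", st)
  f <- reconcile_forest(f, st)
  expect_equal(f[[1]]$nodes[[f[[1]]$root]]$species, "Boreoeutheria")
  expect_equal(f[[1]]$nodes[[f[[1]]$root]]$event, "speciation")

  # Carnivora is not ancestral to human/chimp leaves -> named error
  f2 <- forest_from("(g1_human,g2_chimp)[&&NHX:S=Carnivora];", st)
  expect_error(reconcile_forest(f2, st), "not ancestral",
               class = "ancora_validation_error")
})

test_that("ancestral gene content applies the node/edge rule", {
  st <- toy_tree()
  # one speciation at Boreoeutheria: 1 ancestral gene, all 4 leaves descend
  f <- reconcile_forest(forest_from(
    "((g1_human,g2_chimp),(g3_cat,g4_dog));", st), st)
  ct <- ancestral_gene_content(f, st, "Boreoeutheria")
  expect_equal(nrow(ct$genes), 1)
  expect_equal(ct$genes$kind, "node")
  expect_equal(nrow(ct$descendants[[ct$genes$id]]), 4)
  expect_length(ct$mapping, 4)

  # duplication at Hominidae below a Boreoeutheria speciation:
  # 1 copy at Boreoeutheria, 1 copy (the duplication node) at Hominidae
  f2 <- reconcile_forest(forest_from(
    "(((g1_human,g2_chimp),(g3_human,g4_chimp)),(g5_cat,g6_dog));", st), st)
  expect_equal(nrow(ancestral_gene_content(f2, st, "Boreoeutheria")$genes), 1)
  ct_hom <- ancestral_gene_content(f2, st, "Hominidae")
  expect_equal(nrow(ct_hom$genes), 1)
  expect_equal(ct_hom$genes$kind, "node")
  # all 4 hominid genes map to that single pre-duplication copy
  expect_equal(unname(unique(ct_hom$mapping)), ct_hom$genes$id)

  # family restricted to carnivores: root maps to Carnivora, nothing at
  # Boreoeutheria
  f3 <- reconcile_forest(forest_from("(g1_cat,g2_dog);", st), st)
  expect_equal(nrow(ancestral_gene_content(f3, st, "Boreoeutheria")$genes), 0)
  expect_equal(nrow(ancestral_gene_content(f3, st, "Carnivora")$genes), 1)

  # edge case: human-only gene in a Boreoeutheria-rooted family crosses
  # Hominidae on its path -> edge gene at Hominidae
  f4 <- reconcile_forest(forest_from("(g1_human,(g2_cat,g3_dog));", st), st)
  ct4 <- ancestral_gene_content(f4, st, "Hominidae")
  expect_equal(ct4$genes$kind, "edge")
  expect_equal(ct4$descendants[[ct4$genes$id]]$gene_id, "g1_human")

  expect_error(ancestral_gene_content(f, st, "human"), "internal",
               class = "ancora_validation_error")
})

test_that("informative pairs are exactly those whose path crosses the ancestor", {
  st <- toy_tree()
  # 2-leaf subcase via a fresh 2-species tree
  st2 <- read_species_tree("(a,b)R;")
  ip <- informative_pairs(st2, "R")
  expect_equal(nrow(ip), 1)
  expect_equal(sort(c(ip$a, ip$b)), c("a", "b"))

  # toy tree, Hominidae: every pair except cat-dog
  ip <- informative_pairs(st, "Hominidae")
  got <- sort(paste(ip$a, ip$b))
  expect_setequal(got, c("chimp human", "cat human", "dog human",
                         "cat chimp", "chimp dog"))

  # a human-dog comparison informs every ancestor on the human-dog path
  st3 <- read_species_tree(paste0(
    "(((human,chimp)Hominidae,lemur)Primates,",
    "((dog,wolf)Canidae,cat)Carnivora)Boreoeutheria;"))
  for (anc in c("Primates", "Hominidae", "Carnivora", "Canidae", "Boreoeutheria")) {
    ip <- informative_pairs(st3, anc)
    expect_true(any(ip$a == "dog" & ip$b == "human"),
                label = sprintf("human-dog informative for %s", anc))
  }
  # ...but not ancestors off that path
  st4 <- read_species_tree("(((human,chimp)Hominidae,(cat,dog)Carnivora)Boreo,fish)Root;")
  ip <- informative_pairs(st4, "Carnivora")
  expect_false(any(ip$a == "chimp" & ip$b == "human"))
})

test_that("projection keeps mapped genes in order and drops the rest", {
  g <- quick_genome("x", list(chr1 = c("a+", "x+", "b+")))
  mapping <- c(a = "A", b = "B")
  proj <- project_genome(g, mapping)
  expect_equal(proj$chr1$gene, c("A", "B"))
  expect_equal(proj$chr1$orient, c("+", "+"))

  # empty intersection -> empty projection
  expect_length(project_genome(g, c(z = "Z")), 0)

  # two extant paralogs mapping to one ancestral gene: both kept in order
  g2 <- quick_genome("x", list(chr1 = c("p1+", "q+", "p2-")))
  proj2 <- project_genome(g2, c(p1 = "P", p2 = "P", q = "Q"))
  expect_equal(proj2$chr1$gene, c("P", "Q", "P"))
})

test_that("conserved adjacencies honour orientation and consecutiveness", {
  # identity
  x <- quick_projection(list(c1 = c("A+", "B+", "C+")))
  adj <- conserved_adjacencies(x, x)
  expect_setequal(adj$key, c(adjacency_key("A", "head", "B", "tail"),
                             adjacency_key("B", "head", "C", "tail")))

  # reverse-complement symmetry: A+ B+ matches B- A-
  y <- quick_projection(list(c1 = c("B-", "A-")))
  adj <- conserved_adjacencies(quick_projection(list(c1 = c("A+", "B+"))), y)
  expect_equal(adj$key, adjacency_key("A", "head", "B", "tail"))

  # all four orientation cases of the same physical junction agree
  for (pair in list(c("A+", "B+"), c("B-", "A-"))) {
    adj <- conserved_adjacencies(quick_projection(list(c1 = c("A+", "B+"))),
                                 quick_projection(list(c1 = pair)))
    expect_equal(nrow(adj), 1)
  }
  # flipped-strand variants break the junction
  for (pair in list(c("A+", "B-"), c("A-", "B+"), c("B+", "A+"))) {
    adj <- conserved_adjacencies(quick_projection(list(c1 = c("A+", "B+"))),
                                 quick_projection(list(c1 = pair)))
    expect_equal(nrow(adj), 0)
  }

  # an intervening content gene destroys consecutiveness
  adj <- conserved_adjacencies(quick_projection(list(c1 = c("A+", "B+"))),
                               quick_projection(list(c1 = c("A+", "C+", "B+"))))
  expect_equal(nrow(adj), 0)

  # multi-copy genes are excluded as endpoints in the genome carrying them:
  # with B duplicated in y, every adjacency that touches B disappears, and
  # a fourth gene keeps its junction
  adj <- conserved_adjacencies(
    quick_projection(list(c1 = c("A+", "B+", "C+", "D+"))),
    quick_projection(list(c1 = c("A+", "B+", "C+", "D+", "B+"))))
  expect_equal(adj$key, adjacency_key("C", "head", "D", "tail"))
})

test_that("duplicated endpoints are dropped only in the genome carrying them", {
  adj <- conserved_adjacencies(
    quick_projection(list(c1 = c("A+", "B+", "C+"))),
    quick_projection(list(c1 = c("A+", "B+", "C+"), c2 = c("B-"))))
  # B occurs twice in genome y (chr1 and chr2): no adjacency involving B
  expect_equal(nrow(adj), 0)
})

test_that("graph weights count distinct supporting species pairs", {
  k_ab <- adjacency_key("A", "head", "B", "tail")
  k_bc <- adjacency_key("B", "head", "C", "tail")
  adj <- list(p1 = c(k_ab, k_bc), p2 = k_ab, p3 = k_ab,
              p4 = character(), p5 = character())
  g <- build_adjacency_graph(adj, nodes = c("A", "B", "C", "D"))
  expect_equal(g$edges$weight[g$edges$key == k_ab], 3)
  expect_equal(g$edges$weight[g$edges$key == k_bc], 1)
  # unsupported gene is present with degree 0
  expect_true("D" %in% g$nodes)
  expect_false("D" %in% c(g$edges$a, g$edges$b))

  # same pair supporting the same adjacency twice counts once
  g2 <- build_adjacency_graph(list(p1 = c(k_ab, k_ab)), nodes = c("A", "B"))
  expect_equal(g2$edges$weight, 1)
})
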