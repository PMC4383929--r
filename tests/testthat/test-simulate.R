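# Synthetic-data generators: clade evolution with recorded truth and MAF
# alignments with planted conserved elements.

test_that("zero rates reproduce the root everywhere, trees match the species tree", {
  st <- toy_tree()
  cl <- simulate_clade(20, 2, st, rates = list(), seed = 3)
  for (node in st$nodes)
    expect_identical(cl$state[[node]], cl$state[[st$root]])
  expect_length(cl$forest, 20)
  for (tr in cl$forest) {
    root <- tr$nodes[[tr$root]]
    expect_equal(root$species, "Boreoeutheria")
    expect_equal(root$event, "speciation")
    expect_length(ancora:::gt_leaves(tr), 4)
  }
})

test_that("simulation is byte-for-byte reproducible from its seed", {
  st <- toy_tree()
  a <- simulate_clade(30, 2, st, rates = list(inversion = 1, duplication = 0.5,
                                              loss = 0.5, translocation = 0.5),
                      seed = 12)
  b <- simulate_clade(30, 2, st, rates = list(inversion = 1, duplication = 0.5,
                                              loss = 0.5, translocation = 0.5),
                      seed = 12)
  expect_identical(a$state, b$state)
  expect_identical(write_gene_forest(a$forest), write_gene_forest(b$forest))
  c <- simulate_clade(30, 2, st, rates = list(inversion = 1), seed = 13)
  expect_false(identical(a$state, c$state))
})

test_that("one inversion changes exactly two adjacencies on that branch", {
  st <- toy_tree()
  # high rate on purpose: pick a replicate where exactly one interior
  # inversion hit the branch to the human leaf
  found <- FALSE
  for (seed in 1:20) {
    cl <- simulate_clade(100, 1, st, rates = list(inversion = 0.6), seed = seed)
    ev <- cl$events[["human"]]
    if (length(ev) != 1L) next
    if (ev[[1]]$i == 1L || ev[[1]]$j == nrow(cl$state[["Hominidae"]][[ev[[1]]$chrom]]))
      next
    parent_adj <- clade_adjacency_set(cl, "Hominidae")
    child_adj <- clade_adjacency_set(cl, "human")
    expect_length(setdiff(parent_adj, child_adj), 2)
    expect_length(setdiff(child_adj, parent_adj), 2)
    found <- TRUE
    break
  }
  expect_true(found)
})

test_that("replaying the event log reproduces every stored genome", {
  st <- toy_tree()
  cl <- simulate_clade(60, 3, st,
                       rates = list(inversion = 1.5, translocation = 0.5,
                                    fusion = 0.3, fission = 0.3,
                                    duplication = 0.7, loss = 0.7),
                       seed = 21)
  walk <- function(node) {
    for (child in cl$stree$children[[node]] %||% character()) {
      replayed <- replay_events(cl$state[[node]], cl$events[[child]])
      expect_identical(replayed, cl$state[[child]])
      walk(child)
    }
  }
  walk(st$root)
})

test_that("re-reconciling the emitted forest reproduces its annotations", {
  st <- toy_tree()
  cl <- simulate_clade(40, 2, st,
                       rates = list(inversion = 1, duplication = 1, loss = 0.5),
                       seed = 33)
  # strip all internal annotations, re-reconcile, compare NHX output
  stripped <- lapply(cl$forest, function(tr) {
    for (i in seq_along(tr$nodes)) {
      if (length(tr$nodes[[i]]$children)) {
        tr$nodes[[i]]$species <- NULL
        tr$nodes[[i]]$event <- NULL
      }
    }
    tr
  })
  expect_identical(write_gene_forest(reconcile_forest(stripped, st)),
                   write_gene_forest(cl$forest))
})

test_that("duplications create paralog pairs and losses shrink genomes", {
  st <- toy_tree()
  cl <- simulate_clade(30, 1, st, rates = list(duplication = 2), seed = 2)
  n_dups <- sum(vapply(cl$events, function(evs)
    sum(vapply(evs, function(e) e$type == "duplication", logical(1))), integer(1)))
  expect_gt(n_dups, 0)
  # some extant genome carries more genes than the root
  sizes <- vapply(st$leaves, function(s) nrow(cl$genomes[[s]]$genes), integer(1))
  expect_gt(max(sizes), 30)

  cl2 <- simulate_clade(30, 1, st, rates = list(loss = 2), seed = 2)
  sizes2 <- vapply(st$leaves, function(s) nrow(cl2$genomes[[s]]$genes), integer(1))
  expect_lt(min(sizes2), 30)
})

test_that("written clades are read back consistently by the package readers", {
  st <- toy_tree()
  cl <- simulate_clade(25, 2, st, rates = list(inversion = 1, duplication = 0.5),
                       seed = 44)
  dir <- withr::local_tempdir()
  write_clade(cl, dir)
  st2 <- read_species_tree(file.path(dir, "species_tree.nwk"))
  expect_setequal(st2$leaves, st$leaves)
  forest <- read_gene_forest(file.path(dir, "forest.nhx"), st2)
  expect_length(forest, length(cl$forest))
  g <- read_gene_table(file.path(dir, "genes", "human.tsv"), "human")
  expect_identical(g$genes, cl$genomes$human$genes)
})

test_that("MAF simulation plants perfectly conserved elements with exact truth", {
  sim <- simulate_maf_truth(200, 10, 0.5, planted = list(c(50, 30)), seed = 9)
  expect_length(sim$blocks, 1)
  expect_equal(sim$truth$start, 50)
  expect_equal(sim$truth$end, 80)
  m <- ancora:::maf_char_matrix(sim$blocks[[1]])
  planted_cols <- 51:80
  expect_true(all(m[, planted_cols] == rep(m[1, planted_cols], each = nrow(m))))

  # reference row is ungapped; declared sizes match texts by construction
  expect_false(any(m[1, ] == "-"))

  # determinism
  sim2 <- simulate_maf_truth(200, 10, 0.5, planted = list(c(50, 30)), seed = 9)
  expect_identical(sim$blocks[[1]]$rows, sim2$blocks[[1]]$rows)

  # overlapping or under-separated planted intervals are rejected
  expect_error(simulate_maf_truth(200, 10, 0.5,
                                  planted = list(c(50, 30), c(60, 10)), seed = 1),
               "overlap", class = "ancora_validation_error")
  expect_error(simulate_maf_truth(200, 10, 0.5,
                                  planted = list(c(50, 30), c(82, 10)), seed = 1),
               class = "ancora_validation_error")
})

test_that("background noise alone yields no elements at a fixed seed", {
  sim <- simulate_maf_truth(500, 10, 0.5, planted = NULL, seed = 101)
  p <- column_conservation_profile(sim$blocks[[1]], "hsa")
  expect_equal(nrow(detect_elements(p)), 0)
})

test_that("planted elements overlapping provided CDS are kept by the generator but dropped downstream", {
  sim <- simulate_maf_truth(300, 10, 0.5, planted = list(c(50, 30), c(150, 30)),
                            cds = data.frame(start = 60, end = 70), seed = 5)
  expect_equal(nrow(sim$truth), 2)     # generator keeps both
  cnes <- scan_cnes(sim$blocks, "hsa", "Hsa", annotations = sim$annotations)
  expect_equal(nrow(cnes), 1)          # exclusion filter drops the CDS overlap
  expect_equal(c(cnes$start, cnes$end), c(150, 180))
})

test_that("long alignments split into consecutive blocks that concatenate", {
  sim <- simulate_maf_truth(250, 8, 0.4, planted = list(c(30, 25)), seed = 7,
                            block_size = 100)
  expect_length(sim$blocks, 3)
  expect_equal(vapply(sim$blocks, function(b) b$rows$start[1], numeric(1)),
               c(0, 100, 200))
  joined <- paste(vapply(sim$blocks, function(b) b$rows$text[1], character(1)),
                  collapse = "")
  single <- simulate_maf_truth(250, 8, 0.4, planted = list(c(30, 25)), seed = 7)
  expect_equal(joined, single$blocks[[1]]$rows$text[1])
})
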