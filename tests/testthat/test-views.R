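# Homologous pairs, dotplot backends, karyotype painting, marker lookup.

views_fixture <- function() {
  st <- toy_tree()
  path <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(c(
    "(g1_human,g1_dog);",                      # ortholog pair
    "(g2_human,g3_human);",                    # human paralogs
    "((g4_human,g4_chimp),(g4_cat,g4_dog));"), # full family
    path)
  forest <- reconcile_forest(read_gene_forest(path, st), st)
  list(st = st, forest = forest)
}

test_that("homologous pairs follow LCA event labels per mode", {
  fx <- views_fixture()
  ort <- homologous_pairs(fx$forest, fx$st, "human", "dog", "ortholog")
  expect_true(any(ort$gene_a == "g1_human" & ort$gene_b == "g1_dog"))
  expect_true(any(ort$gene_a == "g4_human" & ort$gene_b == "g4_dog"))
  expect_false(any(ort$gene_a == "g2_human"))  # paralogs not in ortholog mode

  par <- homologous_pairs(fx$forest, fx$st, "human", "human", "paralog")
  expect_equal(nrow(par), 1)
  expect_setequal(c(par$gene_a, par$gene_b), c("g2_human", "g3_human"))

  # descent: ancestral gene paired with extant descendants of one species
  des <- homologous_pairs(fx$forest, fx$st, "Boreoeutheria", "human", "descent")
  expect_true(all(grepl("_human$", des$gene_b)))
  expect_true(any(des$gene_b == "g4_human"))
  expect_error(homologous_pairs(fx$forest, fx$st, "human", "dog", "descent"),
               class = "ancora_usage_error")
})

test_that("dotplots use 1-based ranks and count pairs per chromosome cell", {
  g <- quick_genome("a", list(chr1 = c("a1+", "a2+", "a3+"),
                              chr2 = c("a4+", "a5+")))
  pairs <- data.frame(gene_a = c("a1", "a2", "a3", "a4"),
                      gene_b = c("a1", "a2", "a3", "a4"))
  dp <- matrix_view(g, g, pairs)
  expect_equal(unname(dp$overview["chr1", "chr1"]), 3L)
  expect_equal(unname(dp$overview["chr2", "chr2"]), 1L)
  expect_equal(sum(dp$overview), nrow(pairs))
  # identity comparison: pure diagonal
  d1 <- dp$points[dp$points$chrom_a == "chr1", ]
  expect_equal(d1$rank_a, d1$rank_b)

  # inverted segment shows as an anti-diagonal
  g2 <- quick_genome("b", list(chr1 = c("a1+", "a2+", "a3+", "a4+", "a5+")))
  g2inv <- quick_genome("b", list(chr1 = c("a1+", "a4-", "a3-", "a2-", "a5+")))
  pr <- data.frame(gene_a = paste0("a", 1:5), gene_b = paste0("a", 1:5))
  dpi <- matrix_view(g2, g2inv, pr)
  mid <- dpi$points[dpi$points$rank_a %in% 2:4, ]
  expect_equal(mid$rank_b[order(mid$rank_a)], c(4, 3, 2))

  # empty pair list: all-zero overview, no points
  dp0 <- matrix_view(g, g, pairs[0, ])
  expect_true(all(dp0$overview == 0))
  expect_equal(nrow(dp0$points), 0)

  # absent gene is named in the error
  expect_error(matrix_view(g, g, data.frame(gene_a = "zz", gene_b = "a1")),
               "zz", class = "ancora_validation_error")
})

test_that("karyotype painting colors, smooths and absorbs segments", {
  ga <- quick_genome("a", list(A = paste0("m", 1:10, "+")))
  gb <- quick_genome("b", list(c1 = paste0("x", 1:5, "+"),
                               c2 = paste0("y", 1:5, "+")))
  # one-to-one mapping to a single partner chromosome: one segment
  pairs1 <- data.frame(gene_a = paste0("m", 1:10),
                       gene_b = rep(paste0("x", 1:5), 2))
  kv1 <- karyo_view(ga, gb, pairs1)
  expect_equal(nrow(kv1$A), 1)
  expect_equal(kv1$A$color, "c1")
  expect_equal(c(kv1$A$start_rank, kv1$A$end_rank), c(1, 10))

  # fusion signature: first half one color, second half another -> 2 segments
  pairs2 <- data.frame(gene_a = paste0("m", 1:10),
                       gene_b = c(paste0("x", 1:5), paste0("y", 1:5)))
  kv2 <- karyo_view(ga, gb, pairs2)
  expect_equal(kv2$A$color, c("c1", "c2"))
  expect_equal(kv2$A$start_rank, c(1, 6))
  expect_equal(kv2$A$end_rank, c(5, 10))

  # a minority singleton is smoothed away with window 3
  pairs3 <- data.frame(gene_a = paste0("m", 1:10),
                       gene_b = c("x1", "x2", "y1", "x3", "x4", "x5",
                                  "y2", "y3", "y4", "y5"))
  kv3_raw <- karyo_view(ga, gb, pairs3)
  expect_gt(nrow(kv3_raw$A), 2)
  kv3 <- karyo_view(ga, gb, pairs3, smoothing_window = 3)
  expect_equal(kv3$A$color, c("c1", "c2"))

  # multi-partner genes become unassigned, absorbed when neighbors agree
  pairs4 <- rbind(pairs1, data.frame(gene_a = "m5", gene_b = "y1"))
  kv4 <- karyo_view(ga, gb, pairs4)
  expect_equal(kv4$A$color, "c1")

  # segments partition the chromosome with no same-color neighbors
  for (kv in list(kv2, kv3)) {
    seg <- kv$A
    expect_equal(seg$start_rank[1], 1)
    expect_equal(seg$end_rank[nrow(seg)], 10)
    if (nrow(seg) > 1) {
      expect_true(all(seg$start_rank[-1] == seg$end_rank[-nrow(seg)] + 1))
      expect_true(all(seg$color[-1] != seg$color[-nrow(seg)]))
    }
  }

  expect_error(karyo_view(ga, gb, pairs2, smoothing_window = 2),
               class = "ancora_usage_error")
})

test_that("painting is invariant to chromosome label renaming", {
  ga <- quick_genome("a", list(A = paste0("m", 1:6, "+")))
  gb1 <- quick_genome("b", list(c1 = c("x1+", "x2+", "x3+"),
                                c2 = c("y1+", "y2+", "y3+")))
  gb2 <- quick_genome("b", list(k9 = c("x1+", "x2+", "x3+"),
                                k7 = c("y1+", "y2+", "y3+")))
  pairs <- data.frame(gene_a = paste0("m", 1:6),
                      gene_b = c("x1", "x2", "x3", "y1", "y2", "y3"))
  kv1 <- karyo_view(ga, gb1, pairs)
  kv2 <- karyo_view(ga, gb2, pairs)
  expect_equal(kv1$A[, c("start_rank", "end_rank")],
               kv2$A[, c("start_rank", "end_rank")])
  expect_equal(kv2$A$color, c("k9", "k7"))
})

test_that("marker lookup maps names, handles duplicates and misses", {
  g <- quick_genome("a", list(chr1 = c("p1+", "p2+"), chr2 = c("p3+")))
  pairs <- data.frame(gene_a = c("p1", "p2", "p3", "p3"),
                      gene_b = c("hoxa", "hoxb", "hoxc", "hoxc2"))
  # four markers, one position each
  res <- locate_markers(c("hoxa", "hoxb", "hoxc", "hoxc2"), pairs, g)
  expect_equal(nrow(res$found), 4)
  expect_length(res$not_found, 0)
  # duplicated marker: two positions emitted
  pairs2 <- rbind(pairs, data.frame(gene_a = "p2", gene_b = "hoxa"))
  res2 <- locate_markers("hoxa", pairs2, g)
  expect_equal(nrow(res2$found), 2)
  # unknown name is reported, not an error
  res3 <- locate_markers(c("hoxa", "nope"), pairs, g)
  expect_equal(res3$not_found, "nope")
})

test_that("view JSON writers emit valid, deterministic JSON", {
  g <- quick_genome("a", list(chr1 = c("a1+", "a2+")))
  dp <- matrix_view(g, g, data.frame(gene_a = c("a1", "a2"),
                                     gene_b = c("a1", "a2")))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_view_json(dp, f1, meta = list(seed = 1))
  write_view_json(dp, f2, meta = list(seed = 1))
  expect_identical(readLines(f1), readLines(f2))
  parsed <- jsonlite::read_json(f1)
  expect_equal(parsed$type, "dotplot")
  expect_equal(parsed$meta$seed, 1)
})
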