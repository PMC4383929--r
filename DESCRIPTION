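Package: ancora
Title: Ancestral Gene Orders, Conserved Non-Coding Elements and Synteny Views
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics toolkit for gene-order evolution. Reconstructs
    ancestral gene content and gene order from reconciled gene trees and extant
    gene orders by recording gene adjacencies conserved across informative
    species pairs, combining them in a weighted adjacency graph, greedily
    linearizing the graph into contigs and scaffolding contigs in a second
    round. Detects conserved non-coding elements (CNEs) in multiple-alignment
    (MAF) blocks by per-column conservation profiling, seed detection with
    bounded extension, coding-sequence exclusion and reference-coordinate
    naming, and scores candidate CNE-to-gene regulatory interactions by
    conservation of linkage. Provides pairwise-synteny backends (ortholog and
    paralog dotplots, karyotype painting, marker lookup) and synthetic-data
    generators with recorded ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
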