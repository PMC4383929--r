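---
title: "Ancestral gene order, CNE detection and synteny views: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral gene order, CNE detection and synteny views: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancora)
```

`ancora` implements three connected pieces of gene-order comparative
genomics: reconstruction of ancestral gene order from reconciled gene trees
and extant gene orders, detection of conserved non-coding elements (CNEs) in
multiple alignments with target-gene scoring, and the data backends for
pairwise synteny graphics. This vignette explains the models, the tunable
parameters, the simulators that provide ground truth, and the design choices
made where the methods left genuine freedom.

## Data model

All coordinates are 0-based half-open internally; the GFF3 converters
(`to_gff3_coords()`/`from_gff3_coords()`) are exact inverses and BED output
needs no conversion. A `genome` holds one interval per gene (any
multi-transcript coordinate selection is assumed to have happened upstream),
ordered per chromosome by start with ties broken by gene id, so that "gene
rank" is well defined everywhere. MAF rows keep their strand-relative
coordinates exactly as stored; conversion to forward-strand intervals happens
only when elements are projected.

## Reconciliation and ancestral gene content

Gene trees are reconciled by LCA (most parsimonious) mapping: each internal
node is assigned the last common ancestor of its children's assignments and
labelled a duplication exactly when its assignment equals that of at least
one child. NHX `S=`/`D=` annotations, when present in the input, are kept and
validated (an assignment must be ancestral-or-equal to every child's); this
accommodates pre-reconciled Compara-style forests.

The gene content of an ancestor *A* contains one ancestral gene per tree node
mapped to *A* and one per tree edge whose species interval strictly brackets
*A*. Two corners deserve a note:

- **A duplication node at *A*** contributes *one* ancestral gene — the
  pre-duplication state; the duplicated copies exist strictly below *A*.
  Consequently, in a chain of nodes mapped to the same ancestor only the
  highest contributes, and every extant gene maps to at most one ancestral
  gene of *A* (the mapping `ancestral_gene_content()` returns).
- **Copies invisible to parsimony stay invisible.** If one product of a
  duplication died out, LCA reconciliation will place the duplication lower
  than it really happened; content is computed from the reconciled tree, not
  from any privileged knowledge.

## Adjacencies, the weighted graph and greedy linearization

Reading a chromosome left to right, a `+` gene exposes its *tail* on the left
and its *head* on the right; an adjacency is an unordered pairing of two gene
sides, canonicalized so that `A+ B+` in one genome and `B- A-` in another are
the same object. For each informative pair of extant species — the pairs
whose tree path crosses the ancestor — both projections are scanned for
consecutive gene pairs; ancestral genes occurring more than once in a
projection are skipped as endpoints *in that genome only* (ambiguous copy),
and consecutiveness is evaluated strictly after projection (an intervening
content gene breaks a junction; there is no gap-skipping).

Edge weight is the number of distinct supporting species *pairs* (not
occurrences: one pair supporting a junction on two chromosomes counts once).
Linearization visits edges by weight descending, then canonical edge key
ascending — determinism is a contract, so the tie-break is part of the
definition. An edge is accepted iff both incident sides are free and its
genes lie in different connected components (union-find); accepted edges thus
form simple paths. Each contig is read from its lexicographically smallest
terminal gene, a gene being `+` when its head points in reading direction;
this is a reporting convention only, since adjacency keys are
mirror-invariant.

Round 2 repeats the whole machinery with contigs as units: each projected
chromosome is collapsed into maximal runs of one contig's genes, kept only
when the run follows the contig order exactly (`+`) or exactly reversed
(`-`); other runs are ambiguous and dropped. The linearized contig order is
expanded back into gene order, and blocks are numbered `block_1`, `block_2`,
... by decreasing gene count, then first gene id.

## CNE detection

Column identity is measured against the **reference row** among non-gap rows
(the alignment is reference-projected); the majority-character alternative
was rejected because ties would need arbitrary resolution. All thresholds are
inclusive minima: a column is conserved at identity ≥ 0.90, a seed is a
conserved run of ≥ 10 columns, a reported element spans ≥ 20 reference bp and
≥ 8 species (a species counts when it has at least one non-gap character
inside the element). Extension bridges runs of at most 3 non-conserved
columns when another conserved run follows, so a 3-column gap merges two
seeds and a 4-column gap separates elements; reported intervals begin and end
on conserved columns. Reference-gap columns contribute no projected length.

Coding exclusion is triggered by overlap with the CDS annotation of **any**
annotated species — the conservative reading of exclusion "in all of the
species considered". Elements are detected per MAF block; elements from
different blocks that overlap on the reference are unioned before naming
(union interval, maximum species count, length-weighted mean identity), so
reported CNEs never overlap. Names are release-local:
`Reg` + 3-letter species code + 7-digit counter in (chromosome natural order,
start) order. Cross-release name permanence and cross-block stitching of
elements interrupted by block boundaries are known limitations.

## Linkage scoring

The scoring method behind the original CNE–target predictions is
unpublished; `score_linkage()` therefore implements an explicitly labelled
stand-in, pluggable via its `scorer` argument. The stand-in measures
conservation of linkage: for each candidate (the two reference-flanking
genes plus any gene whose interval contains the CNE), the score is the
fraction of evaluated species — CNE present *and* gene annotation available —
in which a same-family gene lies within K genes (default K = 2) of the CNE's
projected position. The display threshold is strict (`score > 0.9`, so 0.90
exactly is not reported) and each CNE keeps only its best-scoring target,
ties resolved by smaller reference distance, then gene id.

## Views

"Relative position" means gene **rank** — the 1-based index in the
coordinate-sorted order of a chromosome (for ancestral genomes: the position
inside a block). Dotplots count homologous pairs per chromosome cell;
karyotype painting colours each gene by its partner's chromosome, sends genes
with zero or multiple partner chromosomes to `"unassigned"` (ambiguity is
surfaced, not hidden), optionally applies an odd-window majority filter
(ties keep the original colour), and absorbs unassigned runs whose two
flanks agree. Rendering is out of scope; outputs are plain data structures
and JSON.

## Simulators and what passing tests mean

`simulate_clade()` evolves a root order of `n_genes` genes on
`n_chromosomes` chromosomes down the species tree. Event counts per branch
and type are Poisson with the given means, capped (default 10) to keep desk
scale; events are applied in a fixed type order with fully recorded
parameters, so replaying a branch log reproduces the stored child genome
byte-for-byte. Duplications are tandem-only, which keeps adjacency truth
unambiguous; an event with no eligible target (e.g. fission on a genome of
1-gene chromosomes) is an error rather than silently skipped. Emitted
forests carry LCA-consistent annotations (see above), so a
strip-and-reconcile round trip is exact by construction and tested through
the NHX writer/parser.

`simulate_maf_truth()` copies an ungapped random reference into every row
inside planted intervals and, outside them, mutates each column
independently (probability `background_mismatch`) and gaps it (probability
`gap_rate`). Because the reference row is ungapped, truth intervals are
exact in reference coordinates. Planted intervals must be separated by ≥ 4
columns so that bounded extension cannot merge them.

These generators emulate gene-order scrambling and column-level
conservation, not real genome evolution: there is no substitution model, no
rate heterogeneity, no dispersed duplication, no indel realism beyond
uniform gaps, and no alignment error. Passing recovery tests therefore shows
the algorithms implement their definitions and are robust at the stated
noise levels — not that real-data accuracy matches.

## Study conditions and problem sizes

The bundled checks run at the scale a workstation handles in seconds:
detection-threshold sweeps use single 10-species blocks of ~100 columns;
adjacency recovery uses 20 replicate clades of 200 genes on 2 chromosomes
over a 5-species tree with a mean of 2 inversions per branch (median
adjacency precision ≥ 0.95 and recall ≥ 0.80 across replicates); the greedy
linearizer is checked against an independently coded oracle on random graphs
of up to 12 edges; the no-event fixpoint uses 120 genes on 3 chromosomes.
The mismatch probability for threshold sweeps is 0.7, placing expected flank
column identity near 0.37, far below the 0.90 threshold.

## Degenerate inputs and numerical choices

Empty pair lists, empty projections, chromosomes with a single gene,
profiles with no conserved column and graphs with no edges all yield empty
(not error) results; singleton genes become singleton contigs oriented `+`.
Identity comparisons are case-insensitive (soft-masked bases count).
Reproducibility is part of every contract: a seed fully determines simulator
output, and reconstruction is deterministic given its inputs, down to
byte-identical TSV.
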