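# CNE -> target-gene linkage scoring.  The published method behind the
# original linkage scores is not public; the scorer implemented here is an
# explicitly labelled stand-in measuring conservation of linkage: the
# fraction of CNE-bearing, annotated species in which an ortholog of the
# candidate gene lies within K genes of the CNE's location.  The scorer is
# pluggable (`scorer` argument) so an alternative can be swapped in.

# Default per-species linkage predicate: TRUE when a gene of the candidate's
# family lies within K genes of the CNE position on its chromosome.
linkage_within_k <- function(genome, family_id, chrom, pos, K) {
  g <- genome_chromosome(genome, chrom)
  if (!nrow(g)) return(FALSE)
  r <- sum(g$start <= pos)               # insertion rank of the CNE position
  idx <- which(g$family_id == family_id)
  any(idx >= r - K + 1L & idx <= r + K)
}

#' Score candidate regulatory targets of CNEs by conservation of linkage
#'
#' Candidate genes of a CNE are its two reference-flanking genes plus any
#' gene whose reference interval contains the CNE (intronic case).  For each
#' candidate, the score is the fraction of evaluated species (those where the
#' CNE is present and a gene annotation is available) in which an ortholog of
#' the candidate -- a gene of the same family -- lies within `K` genes of the
#' CNE's projected location.  CNEs with no evaluable species are omitted with
#' a warning.
#'
#' @param cnes data.frame from [finalize_cnes()] (`name`, `chrom`, `start`,
#'   `end`).
#' @param ref_genome `genome` of the reference species.
#' @param genomes named list (by species) of `genome` objects used as
#'   per-species gene orders.
#' @param presence data.frame of per-species CNE locations: `cne`, `species`,
#'   `chrom`, `pos` (0-based position of the CNE in that species).
#' @param K neighbourhood size in genes (default 2).
#' @param scorer per-species linkage predicate
#'   `function(genome, family_id, chrom, pos, K) -> logical`; the default is
#'   the conservation-of-linkage stand-in described above.
#' @return data.frame of interactions: `cne`, `gene`, `score`,
#'   `n_species_evaluated`, `ref_distance`, ordered per CNE by decreasing
#'   score (ties: smaller reference distance, then gene id).
#' @export
score_linkage <- function(cnes, ref_genome, genomes, presence, K = 2,
                          scorer = linkage_within_k) {
  out <- list()
  for (i in seq_len(nrow(cnes))) {
    cne <- cnes[i, , drop = FALSE]
    cand <- candidate_targets(cne, ref_genome)
    if (!nrow(cand)) next
    pres <- presence[presence$cne == cne$name & presence$species %in% names(genomes), ,
                     drop = FALSE]
    if (!nrow(pres)) {
      warning(sprintf("CNE %s: no species with both presence and annotation; omitted",
                      cne$name), call. = FALSE)
      next
    }
    for (j in seq_len(nrow(cand))) {
      linked <- vapply(seq_len(nrow(pres)), function(k) {
        scorer(genomes[[pres$species[k]]], cand$family_id[j],
               pres$chrom[k], pres$pos[k], K)
      }, logical(1))
      out[[length(out) + 1L]] <- data.frame(
        cne = cne$name, gene = cand$gene_id[j],
        score = mean(linked), n_species_evaluated = nrow(pres),
        ref_distance = cand$ref_distance[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cne = character(), gene = character(), score = numeric(),
                      n_species_evaluated = integer(), ref_distance = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$cne, -res$score, res$ref_distance, res$gene,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Reference-locus candidates: nearest gene on each side + containing genes.
candidate_targets <- function(cne, ref_genome) {
  g <- genome_chromosome(ref_genome, cne$chrom)
  if (!nrow(g)) return(data.frame())
  dist <- ifelse(g$end <= cne$start, cne$start - g$end,
                 ifelse(g$start >= cne$end, g$start - cne$end, 0))
  contains <- g$start <= cne$start & g$end >= cne$end
  left <- which(g$end <= cne$start)
  right <- which(g$start >= cne$end)
  pick <- unique(c(
    if (length(left)) left[which.max(g$end[left])],
    if (length(right)) right[which.min(g$start[right])],
    which(contains)))
  data.frame(gene_id = g$gene_id[pick], family_id = g$family_id[pick],
             ref_distance = dist[pick], stringsAsFactors = FALSE)
}

#' Apply the display threshold and keep each CNE's most probable target
#'
#' Interactions with a score strictly greater than `threshold` survive; per
#' CNE only the best-scoring target is kept (ties broken by smaller reference
#' distance, then gene id).
#'
#' @param interactions data.frame from [score_linkage()].
#' @param threshold display threshold (default 0.9, strict inequality).
#' @return filtered data.frame, at most one row per CNE.
#' @export
report_interactions <- function(interactions, threshold = 0.9) {
  keep <- interactions[interactions$score > threshold, , drop = FALSE]
  if (!nrow(keep)) return(keep)
  keep <- keep[order(keep$cne, -keep$score, keep$ref_distance, keep$gene,
                     method = "radix"), , drop = FALSE]
  keep <- keep[!duplicated(keep$cne), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}
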