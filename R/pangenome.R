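# Pan-genome partitioning: RBH-graph clustering at a conservative identity
# cutoff, with a conservation-of-gene-order (CGO) tie-break for paralogs.
# This is a deliberately simplified take on weighted-CGO orthology tools:
# the contract is the core / unique-core / singleton partition at the stated
# cutoffs, with gene order consulted only where score ties leave the best
# hit ambiguous.

.protKey <- function(genome_id, protein_id) paste(genome_id, protein_id,
                                                  sep = "\r")

# Best hit per query with CGO tie-break: among hits tied on raw score,
# prefer the subject whose +-3 gene neighborhood is most consistent with the
# neighborhood of the query under the preliminary (score-only) best-hit map.
.bestHitsCGO <- function(hits, ordQ, ordS, prelim) {
  if (nrow(hits) == 0L) return(hits)
  split_idx <- split(seq_len(nrow(hits)), hits$query_id)
  pick <- vapply(split_idx, function(ix) {
    h <- hits[ix, , drop = FALSE]
    top <- ix[h$score == max(h$score)]
    if (length(top) == 1L) return(top)
    q <- hits$query_id[top[1]]
    cgo <- vapply(top, function(k) {
      s <- hits$subject_id[k]
      if (is.na(ordQ[q]) || is.na(ordS[s])) return(0L)
      nbr <- names(ordQ)[!is.na(ordQ) & abs(ordQ - ordQ[q]) <= 3 &
                           names(ordQ) != q]
      part <- prelim[nbr]
      part <- part[!is.na(part)]
      sum(abs(ordS[part] - ordS[s]) <= 3, na.rm = TRUE)
    }, 0L)
    top <- top[cgo == max(cgo)]
    if (length(top) > 1L) {
      h2 <- hits[top, , drop = FALSE]
      top <- top[order(-h2$pct_identity, h2$subject_id)]
    }
    top[1]
  }, 0L)
  hits[pick, , drop = FALSE]
}

.rbhForPair <- function(pa, pb, ordA, ordB, minIdentity, minOverlap,
                        maxEvalue, overlapDenominator) {
  covMode <- if (overlapDenominator == "longer") "longer" else "shorter"
  ab <- searchHomologs(pa, pb, minIdentity = minIdentity,
                       minCov = minOverlap, covMode = covMode,
                       maxEvalue = maxEvalue)
  ba <- searchHomologs(pb, pa, minIdentity = minIdentity,
                       minCov = minOverlap, covMode = covMode,
                       maxEvalue = maxEvalue)
  if (nrow(ab) == 0L || nrow(ba) == 0L)
    return(data.frame(protein_a = character(), protein_b = character()))
  prelimAB <- with(.bestBySide(ab, "query_id"),
                   setNames(subject_id, query_id))
  prelimBA <- with(.bestBySide(ba, "query_id"),
                   setNames(subject_id, query_id))
  bestAB <- .bestHitsCGO(ab, ordA, ordB, prelimAB)
  bestBA <- .bestHitsCGO(ba, ordB, ordA, prelimBA)
  key_ab <- paste(bestAB$query_id, bestAB$subject_id, sep = "\r")
  key_ba <- paste(bestBA$subject_id, bestBA$query_id, sep = "\r")
  keep <- key_ab %in% key_ba
  data.frame(protein_a = bestAB$query_id[keep],
             protein_b = bestAB$subject_id[keep])
}

#' Cluster proteins into orthologous groups across genomes
#'
#' Builds a reciprocal-best-hit graph between every genome pair under the
#' clustering thresholds (default: 65% identity, alignment covering at least
#' 70% of the protein length, E <= 1e-10) and returns the connected
#' components as ortholog clusters; every protein lands in exactly one
#' cluster (unmatched proteins become singleton clusters). Score ties among
#' candidate best hits (paralogs) are resolved by conservation of gene
#' order: the candidate whose flanking +-3 genes agree most with the query's
#' neighborhood wins. Proteins without gene-order information degrade to
#' score-only tie-breaking with a notice.
#'
#' @param genomes list of [GenomeRecord-class] objects (>= 1).
#' @param minIdentity percent identity cutoff (default 65).
#' @param minOverlap overlap fraction cutoff (default 0.70).
#' @param maxEvalue E-value cutoff (default 1e-10).
#' @param overlapDenominator `"longer"` (default; overlap relative to the
#'   longer protein, the stricter reading of "70% of protein sequence
#'   length") or `"shorter"`.
#' @param strict if `TRUE`, components are post-filtered so every retained
#'   cluster satisfies the pairwise identity threshold between all member
#'   pairs that were compared (guards against transitive chaining);
#'   chain-breaking proteins are split off as singletons.
#' @return `data.frame` with columns `cluster_id`, `genome_id`,
#'   `protein_id`; one row per protein.
#' @seealso [partitionPanGenome()]
#' @export
clusterOrthologs <- function(genomes, minIdentity = 65, minOverlap = 0.70,
                             maxEvalue = 1e-10,
                             overlapDenominator = c("longer", "shorter"),
                             strict = FALSE) {
  overlapDenominator <- match.arg(overlapDenominator)
  stopifnot(length(genomes) >= 1L)
  ids <- vapply(genomes, genomeId, "")
  if (anyDuplicated(ids)) stop("genome ids must be unique")
  prots <- lapply(genomes, proteome)
  orders <- lapply(genomes, function(g) {
    pm <- mcols(proteome(g))
    if (is.null(pm$gene_order_index)) {
      message("genome '", genomeId(g),
              "' lacks gene order; tie-break degrades to score-only")
      setNames(rep(NA_real_, length(proteome(g))), names(proteome(g)))
    } else setNames(as.numeric(pm$gene_order_index), names(proteome(g)))
  })
  verts <- unlist(lapply(seq_along(genomes), function(i)
    .protKey(ids[i], names(prots[[i]]))))
  edges <- list()
  if (length(genomes) >= 2L) {
    for (i in 1:(length(genomes) - 1L)) for (j in (i + 1L):length(genomes)) {
      rbh <- .rbhForPair(prots[[i]], prots[[j]], orders[[i]], orders[[j]],
                         minIdentity, minOverlap, maxEvalue,
                         overlapDenominator)
      if (nrow(rbh))
        edges[[length(edges) + 1L]] <- data.frame(
          from = .protKey(ids[i], rbh$protein_a),
          to = .protKey(ids[j], rbh$protein_b))
    }
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character())
  gr <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                      vertices = data.frame(name = verts))
  comp <- igraph::components(gr)$membership
  if (strict) {
    seqs <- setNames(
      do.call(c, lapply(seq_along(genomes), function(i) prots[[i]])),
      verts)
    comp <- .strictSplit(comp, seqs, minIdentity)
  }
  keys <- names(comp)
  gid <- sub("\r.*$", "", keys)
  pid_ <- sub("^[^\r]*\r", "", keys)
  cl <- as.integer(factor(comp, levels = unique(comp[order(gid, pid_)])))
  out <- data.frame(cluster_id = sprintf("OG%05d", cl),
                    genome_id = gid, protein_id = pid_)
  out <- out[order(out$cluster_id, out$genome_id, out$protein_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Strict mode guards against transitive chaining: within every multi-member
# component, all cross-member pairs are re-aligned and only edges meeting
# the identity threshold are kept; the component is re-split into the
# connected components of that pairwise-verified subgraph.
.strictSplit <- function(comp, seqs, minIdentity) {
  mat <- .blosum62()
  nxt <- max(comp) + 1L
  for (cid in unique(comp)) {
    members <- names(comp)[comp == cid]
    if (length(members) < 3L) next
    pairs <- utils::combn(members, 2L)
    ok <- vapply(seq_len(ncol(pairs)), function(k) {
      al <- pairwiseAlignment(seqs[[pairs[1, k]]], seqs[[pairs[2, k]]],
                              type = "local", substitutionMatrix = mat,
                              gapOpening = 11, gapExtension = 1)
      pid(al, type = "PID1") >= minIdentity
    }, TRUE)
    sub <- igraph::graph_from_data_frame(
      data.frame(from = pairs[1, ok], to = pairs[2, ok]),
      directed = FALSE, vertices = data.frame(name = members))
    mem <- igraph::components(sub)$membership
    comp[members] <- nxt + mem
    nxt <- nxt + max(mem) + 1L
  }
  comp
}

#' Partition ortholog clusters into core, unique-core and singletons
#'
#' Computes the Venn-cell occupancy of every cluster: `core` clusters cover
#' all genomes, a `unique core` of a genome subset covers exactly that
#' subset (with >= 2 genomes), and `singletons` are clusters with a single
#' member protein.
#'
#' @param clusters `data.frame` from [clusterOrthologs()].
#' @param genomeIds character vector of all genome ids in the analysis
#'   (defaults to those present in `clusters`).
#' @return list with elements:
#'   `clusters` (the input, plus `n_members` and `genome_set` per cluster id
#'   in `summary`), `summary` (per-cluster data.frame), `venn` (named count
#'   per non-empty genome subset, names are `+`-joined sorted genome ids),
#'   `core_ids`, `singleton_ids`, `n_core`, and `singletons` (data.frame of
#'   singleton proteins with their genome).
#' @export
partitionPanGenome <- function(clusters, genomeIds = NULL) {
  if (is.null(genomeIds)) genomeIds <- sort(unique(clusters$genome_id))
  sets <- vapply(split(clusters$genome_id, clusters$cluster_id),
                 function(g) paste(sort(unique(g)), collapse = "+"), "")
  sizes <- vapply(split(clusters$protein_id, clusters$cluster_id),
                  length, 0L)
  summary <- data.frame(cluster_id = names(sets), genome_set = unname(sets),
                        n_members = unname(sizes[names(sets)]))
  venn <- table(sets)
  venn <- setNames(as.integer(venn), names(venn))
  all_key <- paste(sort(genomeIds), collapse = "+")
  core_ids <- summary$cluster_id[summary$genome_set == all_key]
  singleton_ids <- summary$cluster_id[summary$n_members == 1L]
  singles <- clusters[clusters$cluster_id %in% singleton_ids, , drop = FALSE]
  list(clusters = clusters, summary = summary, venn = venn,
       genome_ids = genomeIds,
       core_ids = core_ids, n_core = length(core_ids),
       singleton_ids = singleton_ids,
       singletons = singles)
}

#' Unique-core cluster count for a genome subset
#'
#' @param partition result of [partitionPanGenome()].
#' @param genomeSubset character vector of genome ids.
#' @return number of clusters whose genome set is exactly `genomeSubset`.
#' @export
uniqueCore <- function(partition, genomeSubset) {
  key <- paste(sort(genomeSubset), collapse = "+")
  n <- partition$venn[key]
  if (is.na(n)) 0L else unname(n)
}

#' Fraction of a genome's singletons that lie on plasmids
#'
#' Only meaningful for genomes with labelled replicons (complete genomes);
#' for a draft genome whose replicons are all contigs the fraction is not
#' computable and `NA` is returned with a message.
#'
#' @param partition result of [partitionPanGenome()].
#' @param genome the [GenomeRecord-class] of interest.
#' @return percentage (0--100) of that genome's singleton proteins whose
#'   replicon is a plasmid, rounded to integer; `NA` if replicons are
#'   unlabelled or the genome has no singletons.
#' @export
singletonRepliconFraction <- function(partition, genome) {
  kinds <- repliconKind(genome)
  if (!any(kinds %in% c("chromosome", "plasmid"))) {
    message("genome '", genomeId(genome),
            "' has unlabelled replicons; plasmid fraction not computable")
    return(NA_real_)
  }
  sg <- partition$singletons
  sg <- sg[sg$genome_id == genomeId(genome), , drop = FALSE]
  if (nrow(sg) == 0L) return(NA_real_)
  pm <- mcols(proteome(genome))
  rep_of <- setNames(pm$replicon_id, names(proteome(genome)))
  on_plasmid <- kinds[rep_of[sg$protein_id]] == "plasmid"
  round(100 * sum(on_plasmid) / nrow(sg))
}
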