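#' Configuration for the end-to-end comparison pipeline
#'
#' Thresholds default to the study values used throughout the package:
#' ortholog clustering at 65% identity / 70% overlap / E 1e-10, trait
#' screening at 30% identity / E 1e-6, a 20-kb cassette window and 1000
#' bootstrap replicates.
#'
#' @param clusterIdentity,clusterOverlap,clusterEvalue pan-genome
#'   clustering thresholds.
#' @param aaiIdentity,aaiCov,aaiEvalue AAI thresholds.
#' @param screenIdentity,screenEvalue trait-screen thresholds.
#' @param cassetteWindow cassette window in bp.
#' @param bootstrap bootstrap replicates for the tree stage.
#' @param seed RNG seed for all resampling.
#' @return named list (validated).
#' @export
pipelineConfig <- function(clusterIdentity = 65, clusterOverlap = 0.70,
                           clusterEvalue = 1e-10, aaiIdentity = 30,
                           aaiCov = 0.7, aaiEvalue = 1e-6,
                           screenIdentity = 30, screenEvalue = 1e-6,
                           cassetteWindow = 20000, bootstrap = 1000,
                           seed = 1) {
  stopifnot(clusterIdentity >= 0, clusterIdentity <= 100,
            clusterOverlap > 0, clusterOverlap <= 1,
            aaiIdentity >= 0, aaiCov > 0, aaiCov <= 1,
            screenIdentity >= 0, cassetteWindow > 0, bootstrap >= 1)
  list(clusterIdentity = clusterIdentity, clusterOverlap = clusterOverlap,
       clusterEvalue = clusterEvalue, aaiIdentity = aaiIdentity,
       aaiCov = aaiCov, aaiEvalue = aaiEvalue,
       screenIdentity = screenIdentity, screenEvalue = screenEvalue,
       cassetteWindow = cassetteWindow, bootstrap = bootstrap, seed = seed)
}

# Concatenate single-copy core families into a pseudo-alignment. Valid when
# family members are equal length (substitution-only families, as the
# synthetic generator produces); families with length variation are skipped
# with a notice, since real alignment is out of scope here.
.coreAlignment <- function(genomes, partition) {
  ids <- vapply(genomes, genomeId, "")
  cl <- partition$clusters
  rows <- setNames(rep("", length(ids)), ids)
  used <- 0L
  for (cid in partition$core_ids) {
    m <- cl[cl$cluster_id == cid, , drop = FALSE]
    if (nrow(m) != length(ids) || anyDuplicated(m$genome_id)) next
    seqs <- vapply(ids, function(g) {
      gi <- which(ids == g)
      as.character(proteome(genomes[[gi]])[[
        m$protein_id[m$genome_id == g]]])
    }, "")
    if (length(unique(nchar(seqs))) != 1L) {
      message("core family ", cid, " has length variation; skipped from ",
              "the concatenated alignment")
      next
    }
    rows <- paste0(rows, seqs)
    used <- used + 1L
  }
  if (used < 1L || any(nchar(rows) == 0L)) return(NULL)
  AAStringSet(setNames(rows, ids))
}

#' Run the full comparison pipeline on a set of genomes
#'
#' Orchestrates every stage: per-genome statistics (size, GC%, median
#' proteome pI), the delta* signature matrix, the AAI matrix, pan-genome
#' clustering and partitioning (with plasmid-origin singleton fractions for
#' genomes with labelled replicons), the trait table (LuxI/LuxR counts and
#' solos, Nqr presence, ectoine cassette, Rieske spacings of dioxygenase
#' hits), and a bootstrap NJ tree built from the Poisson distances of the
#' concatenated single-copy core families (or of `alignment` if supplied).
#' Writes TSV/JSON/Newick outputs plus a manifest recording thresholds,
#' seed and package version when `outputDir` is given. A failing stage is
#' recorded in the manifest and leaves its slot `NULL` rather than aborting
#' the bundle.
#'
#' @param genomes list of [GenomeRecord-class] objects (or a directory of
#'   `.gbk` files).
#' @param config from [pipelineConfig()].
#' @param outputDir optional output directory.
#' @param alignment optional pre-aligned `AAStringSet` for the tree stage.
#' @return list: `stats`, `delta`, `aai`, `partition`, `traits`, `tree`,
#'   `manifest` (invisible when writing to disk).
#' @export
runPipeline <- function(genomes, config = pipelineConfig(),
                        outputDir = NULL, alignment = NULL) {
  if (is.character(genomes) && length(genomes) == 1L && dir.exists(genomes)) {
    files <- sort(list.files(genomes, pattern = "\\.(gb|gbk|gbff)$",
                             full.names = TRUE))
    genomes <- lapply(files, readGenome)
  }
  ids <- vapply(genomes, genomeId, "")
  manifest <- list(package = "novocomp",
                   version = as.character(packageVersion("novocomp")),
                   genomes = ids, thresholds = config, seed = config$seed,
                   failures = list())
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failures[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  res$stats <- stage("stats", {
    st <- genomeStats(genomes)
    st$median_pI <- vapply(genomes, medianProteomePI, 0)
    st
  })
  res$delta <- stage("signature", signatureMatrix(genomes))
  res$aai <- if (length(genomes) >= 2L) {
    stage("aai", aaiMatrix(genomes, minIdentity = config$aaiIdentity,
                           minCov = config$aaiCov,
                           maxEvalue = config$aaiEvalue))
  } else {
    message("single genome: pairwise stages skipped")
    NULL
  }
  res$partition <- if (length(genomes) >= 2L) {
    stage("pangenome", {
      cl <- clusterOrthologs(genomes, minIdentity = config$clusterIdentity,
                             minOverlap = config$clusterOverlap,
                             maxEvalue = config$clusterEvalue)
      part <- partitionPanGenome(cl, ids)
      part$plasmid_singleton_pct <- setNames(vapply(genomes, function(g)
        suppressMessages(singletonRepliconFraction(part, g)), 0), ids)
      part
    })
  } else NULL
  res$traits <- stage("traits", .traitTable(genomes, config))
  res$tree <- stage("tree", {
    aln <- if (!is.null(alignment)) alignment else {
      if (is.null(res$partition)) NULL else
        .coreAlignment(genomes, res$partition)
    }
    if (is.null(aln)) {
      message("no usable alignment; tree stage skipped")
      NULL
    } else if (length(aln) >= 3L) {
      bootstrapTree(aln, replicates = config$bootstrap, seed = config$seed)
    } else NULL
  })
  res$manifest <- manifest

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    wtsv <- function(x, f) write.table(x, file.path(outputDir, f),
                                       sep = "\t", quote = FALSE)
    if (!is.null(res$stats))
      write.table(res$stats, file.path(outputDir, "genome_stats.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$delta)) wtsv(round(res$delta, 1), "delta_matrix.tsv")
    if (!is.null(res$aai)) wtsv(round(res$aai, 1), "aai_matrix.tsv")
    if (!is.null(res$partition)) {
      write.table(res$partition$clusters,
                  file.path(outputDir, "clusters.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      venn <- data.frame(genome_set = names(res$partition$venn),
                         n_clusters = as.integer(res$partition$venn))
      write.table(venn, file.path(outputDir, "venn_cells.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$traits))
      write.table(res$traits, file.path(outputDir, "traits.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$tree))
      ape::write.tree(res$tree, file.path(outputDir, "tree.nwk"))
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}

.traitTable <- function(genomes, config) {
  luxI <- referenceSet("luxI")
  luxR <- referenceSet("luxR")
  nqr <- referenceSet("nqr")
  ardo <- referenceSet("ardo")
  ect <- list(EctA = referenceSet("ectA"), EctB = referenceSet("ectB"),
              EctC = referenceSet("ectC"))
  do.call(rbind, lapply(genomes, function(g) {
    scr <- function(rs) screenProteome(g, rs,
                                       minIdentity = config$screenIdentity,
                                       maxEvalue = config$screenEvalue)
    hi <- scr(luxI)
    solos <- luxRSolos(g, luxRSet = luxR, luxISet = luxI,
                       minIdentity = config$screenIdentity,
                       maxEvalue = config$screenEvalue)
    hn <- scr(nqr)
    ha <- scr(ardo)
    spacings <- if (nrow(ha)) {
      sp <- vapply(ha$query_id, function(p)
        as.integer(rieskeSpacing(proteome(g)[[p]])), 0L)
      paste(sp[!is.na(sp)], collapse = ",")
    } else ""
    cass <- detectCassette(g, ect, window = config$cassetteWindow,
                           minIdentity = config$screenIdentity,
                           maxEvalue = config$screenEvalue)
    data.frame(
      genome_id = genomeId(g),
      n_luxI = nrow(hi),
      n_luxR = nrow(solos),
      n_luxR_solo = sum(solos$solo),
      nqr_present = nrow(hn) > 0,
      ectoine_cassette = cass$complete,
      rieske_spacings = spacings,
      gc_pct = round(gcContent(g), 2),
      median_pI = round(medianProteomePI(g), 2)
    )
  }))
}
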