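# Whole-scenario generator: multiple genomes with planted ortholog families,
# singletons, trait markers and plasmid assignments, emitted as GenomeRecord
# objects (and optionally GenBank files) together with a ground-truth object
# sufficient to check every downstream stage.

#' Specify a synthetic comparative-genomics scenario
#'
#' Builds (and validates) the specification consumed by [buildScenario()].
#' All counts and rates default to a small, fast configuration; see
#' [defaultScenario()] for the six-genome study-shaped default.
#'
#' @param genomes character vector of genome ids (>= 1).
#' @param genomeLength chromosome length in bp, single value or named per
#'   genome (default 50000).
#' @param markov either one `list(trans = , init = )` shared by all genomes
#'   or a named list per genome; `trans` must be 4x4 row-stochastic.
#'   Default: slightly CG-depleted chains that differ between genomes.
#' @param nCoreFamilies ortholog families present in every genome.
#' @param coreIdentity expected pairwise identity within core families.
#' @param uniqueCore named list mapping a `+`-joined sorted genome subset
#'   (e.g. `"g1+g2"`) to a count of families present in exactly that subset.
#' @param uniqueIdentity identity within unique-core families.
#' @param nSingletons per-genome singleton count, single value or named.
#' @param plasmids named list: genome id -> `list(length = bp,
#'   singletonFraction = f)`; that genome gains a plasmid replicon carrying
#'   `round(f * nSingletons)` of its singletons.
#' @param markers list of marker specifications, each a list with `kind`
#'   (`"luxI"`, `"luxRsolo"`, `"rieske"`, `"ectABC"`), `genomes` (ids), and
#'   kind-specific fields: `identity` (to the reference; default 0.6 for
#'   luxI, 0.8 otherwise), `triadIntact` (luxI; default `TRUE`),
#'   `spacing` (rieske; default 17). Each `luxI` marker also plants a
#'   cognate LuxR gene adjacent to it.
#' @param proteinLengthRange min/max family protein length (aa).
#' @param seed mandatory RNG seed.
#' @return validated scenario specification (list).
#' @export
scenarioSpec <- function(genomes, genomeLength = 50000, markov = NULL,
                         nCoreFamilies = 5, coreIdentity = 0.9,
                         uniqueCore = list(), uniqueIdentity = 0.9,
                         nSingletons = 2, plasmids = list(),
                         markers = list(),
                         proteinLengthRange = c(120, 250), seed) {
  if (missing(seed)) stop("a seed is mandatory for scenario generation")
  stopifnot(length(genomes) >= 1L, !anyDuplicated(genomes))
  if (is.null(names(genomeLength)))
    genomeLength <- setNames(rep_len(genomeLength, length(genomes)), genomes)
  if (is.null(markov)) {
    markov <- lapply(seq_along(genomes), function(i) {
      list(trans = .defaultChain(0.05 * i), init = NULL)
    })
    names(markov) <- genomes
  } else if (!is.null(markov$trans)) {
    markov <- setNames(rep(list(markov), length(genomes)), genomes)
  }
  for (g in genomes) {
    if (!.validStochastic(markov[[g]]$trans))
      stop("markov transition matrix for '", g, "' is not row-stochastic")
  }
  if (is.null(names(nSingletons)))
    nSingletons <- setNames(rep_len(nSingletons, length(genomes)), genomes)
  stopifnot(coreIdentity > 0, coreIdentity <= 1,
            uniqueIdentity > 0, uniqueIdentity <= 1)
  for (key in names(uniqueCore)) {
    gs <- strsplit(key, "+", fixed = TRUE)[[1]]
    if (!all(gs %in% genomes))
      stop("uniqueCore subset '", key, "' names unknown genomes")
  }
  for (mk in markers) {
    if (!mk$kind %in% c("luxI", "luxRsolo", "rieske", "ectABC"))
      stop("unknown marker kind: ", mk$kind)
    if (!all(mk$genomes %in% genomes))
      stop("marker '", mk$kind, "' names unknown genomes")
  }
  for (g in names(plasmids)) {
    if (!g %in% genomes) stop("plasmid entry for unknown genome '", g, "'")
  }
  list(genomes = genomes, genomeLength = genomeLength, markov = markov,
       nCoreFamilies = nCoreFamilies, coreIdentity = coreIdentity,
       uniqueCore = uniqueCore, uniqueIdentity = uniqueIdentity,
       nSingletons = nSingletons, plasmids = plasmids, markers = markers,
       proteinLengthRange = proteinLengthRange, seed = seed)
}

# CG-depleted chain with a tunable tilt so genomes differ in signature.
.defaultChain <- function(tilt = 0) {
  base <- matrix(0.25, 4, 4, dimnames = list(.BASES, .BASES))
  base["C", "G"] <- 0.10
  base["C", "A"] <- 0.25 + tilt
  base["C", "C"] <- 0.25 + (0.15 - tilt) / 2
  base["C", "T"] <- 0.25 + (0.15 - tilt) / 2
  base["A", "A"] <- 0.25 + tilt / 2
  base["A", "T"] <- 0.25 - tilt / 2
  base / rowSums(base)
}

#' Build a synthetic scenario
#'
#' Generates every genome of the specification: Markov-chain nucleotide
#' replicons, planted ortholog families (core, unique-core per subset,
#' singletons), and trait markers laid out as CDS features in a defined gene
#' order (cassette genes adjacent; each planted LuxI adjacent to its cognate
#' LuxR; LuxR "solos" kept more than 5 genes from any LuxI). Generation is
#' fully deterministic under the specification seed.
#'
#' @param spec a specification from [scenarioSpec()].
#' @return list with `genomes` (named list of [GenomeRecord-class]) and
#'   `truth`, containing `expected_profiles` (analytic
#'   [DinucProfile-class] per genome), `memberships` (data.frame: family,
#'   category, genome_id, protein_id, replicon kind), `markers` (per planted
#'   marker: genome, protein ids, parameters), `plasmid_singleton_fraction`
#'   (named, planted percentage), and the spec itself.
#' @seealso [writeScenario()], [defaultScenario()]
#' @export
buildScenario <- function(spec) {
  set.seed(spec$seed)
  G <- spec$genomes
  lenr <- spec$proteinLengthRange
  fam_len <- function() sample(lenr[1]:lenr[2], 1L)
  rows <- list()   # per-protein rows: genome, protein, family, category, block
  addRow <- function(genome, pid, seq, family, category, block,
                     replicon = "chromosome") {
    rows[[length(rows) + 1L]] <<- data.frame(
      genome_id = genome, protein_id = pid, seq = seq, family = family,
      category = category, block = block, replicon = replicon)
  }
  pcount <- setNames(rep(0L, length(G)), G)
  nextId <- function(g) {
    pcount[g] <<- pcount[g] + 1L
    sprintf("%s_p%04d", g, pcount[g])
  }

  # core families
  for (f in seq_len(spec$nCoreFamilies)) {
    fam <- genOrthologFamily(fam_len(), length(G), spec$coreIdentity)
    for (i in seq_along(G))
      addRow(G[i], nextId(G[i]), fam$proteins[i], sprintf("core%03d", f),
             "core", NA)
  }
  # unique-core families per subset
  for (key in names(spec$uniqueCore)) {
    gs <- strsplit(key, "+", fixed = TRUE)[[1]]
    for (f in seq_len(spec$uniqueCore[[key]])) {
      fam <- genOrthologFamily(fam_len(), length(gs), spec$uniqueIdentity)
      fid <- sprintf("uc_%s_%03d", gsub("\\+", "_", key), f)
      for (i in seq_along(gs))
        addRow(gs[i], nextId(gs[i]), fam$proteins[i], fid, "unique_core", NA)
    }
  }
  # singletons (plasmid-assigned where configured)
  for (g in G) {
    n <- spec$nSingletons[[g]]
    if (n == 0L) next
    n_pl <- 0L
    if (!is.null(spec$plasmids[[g]]))
      n_pl <- round(spec$plasmids[[g]]$singletonFraction * n)
    for (k in seq_len(n)) {
      seq <- paste(sample(.AA20, fam_len(), TRUE, prob = .AA_BG),
                   collapse = "")
      addRow(g, nextId(g), seq, sprintf("%s_sing%03d", g, k), "singleton",
             NA, replicon = if (k <= n_pl) "plasmid" else "chromosome")
    }
  }
  # markers
  marker_truth <- list()
  luxI_ref <- as.character(referenceSet("luxI")$proteins[[1]])
  luxR_ref <- as.character(referenceSet("luxR")$proteins[[1]])
  blk <- 0L
  mi <- 0L
  for (mk in spec$markers) {
    mi <- mi + 1L
    for (g in mk$genomes) {
      blk <- blk + 1L
      block_id <- sprintf("blk%03d", blk)
      if (mk$kind == "luxI") {
        idn <- if (is.null(mk$identity)) 0.6 else mk$identity
        intact <- if (is.null(mk$triadIntact)) TRUE else mk$triadIntact
        pid_i <- nextId(g)
        addRow(g, pid_i, genLuxILike(idn, triadIntact = intact),
               paste0("luxI_", block_id), "marker_luxI", block_id)
        pid_r <- nextId(g)
        addRow(g, pid_r, .mutateFrom(luxR_ref, 0.7),
               paste0("luxR_", block_id), "marker_luxR", block_id)
        marker_truth[[length(marker_truth) + 1L]] <- list(
          kind = "luxI", genome = g, protein_id = pid_i,
          cognate_luxR = pid_r, triad_intact = intact, identity = idn)
      } else if (mk$kind == "luxRsolo") {
        pid_r <- nextId(g)
        addRow(g, pid_r, .mutateFrom(luxR_ref, 0.7),
               paste0("luxRsolo_", block_id), "marker_luxRsolo", "SOLO")
        marker_truth[[length(marker_truth) + 1L]] <- list(
          kind = "luxRsolo", genome = g, protein_id = pid_r)
      } else if (mk$kind == "rieske") {
        sp <- if (is.null(mk$spacing)) 17L else mk$spacing
        pid_r <- nextId(g)
        addRow(g, pid_r, genArdoLike(spacing = sp),
               paste0("rieske_", block_id), "marker_rieske", NA)
        marker_truth[[length(marker_truth) + 1L]] <- list(
          kind = "rieske", genome = g, protein_id = pid_r, spacing = sp)
      } else if (mk$kind == "ectABC") {
        # 0.9 to the reference keeps cross-genome cassette copies (pairwise
        # ~0.81) comfortably above the 65% clustering cutoff
        idn <- if (is.null(mk$identity)) 0.9 else mk$identity
        pids <- character(3)
        comps <- c("ectA", "ectB", "ectC")
        for (ci in seq_along(comps)) {
          ref <- as.character(referenceSet(comps[ci])$proteins[[1]])
          pids[ci] <- nextId(g)
          addRow(g, pids[ci], .mutateFrom(ref, idn),
                 sprintf("%s_mk%02d", comps[ci], mi),
                 paste0("marker_", comps[ci]), block_id)
        }
        marker_truth[[length(marker_truth) + 1L]] <- list(
          kind = "ectABC", genome = g, protein_ids = pids, identity = idn)
      }
    }
  }

  tab <- do.call(rbind, rows)
  # observable plasmid-singleton fraction: genes whose family has a single
  # member genome-wide are the clusters the pan-genome stage will call
  # singletons (genome-specific markers included)
  fam_size <- table(tab$family)
  plasmid_truth <- setNames(rep(NA_real_, length(G)), G)
  for (g in G) {
    if (is.null(spec$plasmids[[g]])) next
    tg <- tab[tab$genome_id == g & fam_size[tab$family] == 1L, ,
              drop = FALSE]
    if (nrow(tg) > 0L)
      plasmid_truth[g] <- round(100 * mean(tg$replicon == "plasmid"))
  }
  genomes_out <- list()
  for (g in G) {
    tg <- tab[tab$genome_id == g, , drop = FALSE]
    genomes_out[[g]] <- .assembleGenome(g, tg, spec)
  }
  memberships <- tab[, c("family", "category", "genome_id", "protein_id",
                         "replicon")]
  rownames(memberships) <- NULL
  profiles <- lapply(G, function(g)
    expectedDinucProfile(spec$markov[[g]]$trans, genomeId = g))
  names(profiles) <- G
  list(genomes = genomes_out,
       truth = list(expected_profiles = profiles, memberships = memberships,
                    markers = marker_truth,
                    plasmid_singleton_fraction = plasmid_truth,
                    spec = spec))
}

# Lay one genome out: order genes (marker blocks kept contiguous, solos kept
# away from luxI blocks), place CDS back-to-back with 50 bp spacers, check
# feasibility, generate replicon sequences, return a GenomeRecord.
.assembleGenome <- function(g, tg, spec) {
  ordered <- list()
  for (rep_kind in unique(tg$replicon)) {
    tr <- tg[tg$replicon == rep_kind, , drop = FALSE]
    blocks <- split(seq_len(nrow(tr)),
                    ifelse(is.na(tr$block), paste0("s", seq_len(nrow(tr))),
                           tr$block))
    solo <- vapply(blocks, function(ix) any(tr$block[ix] %in% "SOLO"), TRUE)
    haslux <- vapply(blocks, function(ix)
      any(grepl("^marker_lux", tr$category[ix]) & !(tr$block[ix] %in% "SOLO")),
      TRUE)
    others <- blocks[!solo]
    ord <- sample(length(others))
    # keep luxI blocks out of the tail so an appended solo is > 5 genes away
    if (any(haslux[!solo]) && length(others) > 3L) {
      is_lux <- haslux[!solo][ord]
      ord <- c(ord[is_lux], ord[!is_lux])
    }
    idx <- unlist(others[ord], use.names = FALSE)
    idx <- c(idx, unlist(blocks[solo], use.names = FALSE))
    ordered[[rep_kind]] <- tr[idx, , drop = FALSE]
  }
  # coordinates and replicon sequences
  prot <- character()
  info <- list()
  rep_seqs <- character()
  rep_kinds <- character()
  for (rep_kind in names(ordered)) {
    tr <- ordered[[rep_kind]]
    rid <- if (rep_kind == "chromosome") paste0(g, "_chr") else
      paste0(g, "_pl1")
    rlen <- if (rep_kind == "chromosome") spec$genomeLength[[g]] else
      spec$plasmids[[g]]$length
    if (is.null(rlen)) rlen <- 20000L
    pos <- 1L
    for (k in seq_len(nrow(tr))) {
      nt <- 3L * (nchar(tr$seq[k]) + 1L)
      start <- pos + 50L
      end <- start + nt - 1L
      if (end > rlen)
        stop("infeasible layout: genes exceed replicon '", rid, "' (",
             rlen, " bp)")
      prot[tr$protein_id[k]] <- tr$seq[k]
      info[[length(info) + 1L]] <- data.frame(
        replicon_id = rid, gene_order_index = k - 1L,
        start = start, end = end,
        strand = if (k %% 7 == 0) "-" else "+")
      pos <- end
    }
    rep_seqs[rid] <- genMarkovSequence(rlen, spec$markov[[g]]$trans,
                                       init = spec$markov[[g]]$init)
    rep_kinds[rid] <- rep_kind
  }
  GenomeRecord(g, DNAStringSet(rep_seqs), kind = rep_kinds,
               proteome = AAStringSet(prot),
               proteinInfo = do.call(rbind, info))
}

#' The six-genome study-shaped default scenario
#'
#' Mirrors the shape of the comparative study this package is designed
#' around: six genomes, a "marine pair" sharing a large unique core, an
#' ectoine (ectABC) cassette and near-identical genome signatures; an
#' "epiphyte" genome carrying a single AHL synthase; one genome with a
#' plasmid holding half of its singletons; planted Rieske proteins with
#' 17- and 19-residue spacings; and a LuxR solo on the plasmid-bearing
#' marine genome. Five LuxI genes are planted in total across four genomes.
#'
#' @param seed RNG seed (mandatory).
#' @param scale multiplier on family counts for heavier runs (default 1).
#' @return a specification for [buildScenario()].
#' @export
defaultScenario <- function(seed, scale = 1) {
  g <- c("marineA", "marineB", "epiphyte", "rhizo", "subsurface", "effluent")
  chains <- list(
    marineA = list(trans = .defaultChain(0.02), init = NULL),
    marineB = list(trans = .defaultChain(0.025), init = NULL),
    epiphyte = list(trans = .defaultChain(0.08), init = NULL),
    rhizo = list(trans = .defaultChain(0.12), init = NULL),
    subsurface = list(trans = .defaultChain(0.16), init = NULL),
    effluent = list(trans = .defaultChain(0.20), init = NULL)
  )
  scenarioSpec(
    genomes = g,
    genomeLength = 60000,
    markov = chains,
    nCoreFamilies = round(10 * scale), coreIdentity = 0.85,
    uniqueCore = list("marineA+marineB" = round(6 * scale),
                      "effluent+subsurface" = round(2 * scale)),
    uniqueIdentity = 0.9,
    nSingletons = 6,
    plasmids = list(marineB = list(length = 25000, singletonFraction = 0.5)),
    markers = list(
      list(kind = "luxI", genomes = c("marineA", "epiphyte", "rhizo")),
      list(kind = "luxI", genomes = c("marineB", "marineB")),
      list(kind = "luxRsolo", genomes = "marineB"),
      list(kind = "rieske", genomes = "subsurface", spacing = 17),
      list(kind = "rieske", genomes = "marineA", spacing = 19),
      list(kind = "ectABC", genomes = c("marineA", "marineB"))
    ),
    seed = seed
  )
}

#' Write a built scenario to disk
#'
#' Emits one GenBank file per genome, one protein FASTA per genome, and a
#' `ground_truth.json` with the membership table, marker list and expected
#' rho* values.
#'
#' @param scenario result of [buildScenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(scenario$genomes)) {
    writeGenBank(scenario$genomes[[g]], file.path(dir, paste0(g, ".gbk")))
    writeProteome(scenario$genomes[[g]],
                  file.path(dir, paste0(g, ".faa")))
  }
  truth <- scenario$truth
  json <- list(
    memberships = truth$memberships,
    markers = truth$markers,
    plasmid_singleton_fraction = as.list(truth$plasmid_singleton_fraction),
    expected_rho = lapply(truth$expected_profiles, function(p)
      as.list(rhoValues(p))),
    seed = truth$spec$seed
  )
  jsonlite::write_json(json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
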