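#' Load a shipped reference protein set
#'
#' The package ships small curated reference sets used by the trait screens:
#' AHL synthases (`luxI`), AHL-responsive regulators (`luxR`), the
#' sodium-pumping NADH dehydrogenase subunits (`nqr`), the ectoine
#' biosynthesis enzymes (`ectA`, `ectB`, `ectC`) and ring-hydroxylating
#' dioxygenase alpha subunits with canonical Rieske sites (`ardo`). These
#' are synthetic reconstructions (see the manifest's provenance column):
#' sequences constructed to carry the diagnostic features of each family --
#' the LuxI Arg24/Phe28/Trp34 triad, Rieske C-X-H-X(n)-C-X-X-H sites -- not
#' database downloads.
#'
#' @param name one of `"luxI"`, `"luxR"`, `"nqr"`, `"ectA"`, `"ectB"`,
#'   `"ectC"`, `"ardo"`.
#' @return list with `name`, `proteins` (named `AAStringSet`) and
#'   `manifest` (data.frame: id, set, component, provenance).
#' @export
referenceSet <- function(name = c("luxI", "luxR", "nqr", "ectA", "ectB",
                                  "ectC", "ardo")) {
  name <- match.arg(name)
  dir <- system.file("extdata", "refsets", package = "novocomp",
                     mustWork = TRUE)
  man <- read.delim(file.path(dir, "manifest.tsv"))
  man <- man[man$set == name, , drop = FALSE]
  if (nrow(man) == 0L) stop("empty reference set: ", name)
  prot <- readAAStringSet(file.path(dir, paste0("synthetic_", name, ".faa")))
  names(prot) <- sub("\\s.*$", "", names(prot))
  list(name = name, proteins = prot, manifest = man)
}

#' Screen a proteome against a reference set
#'
#' Homology search of the proteome (queries) against the reference set under
#' the screening thresholds (default: identity > 30%, E < 1e-6, no coverage
#' requirement), keeping the best reference per query. An empty result is a
#' meaningful negative (e.g. absence of the Nqr sodium pump in a genome).
#'
#' @param proteomeSet named `AAStringSet` or a [GenomeRecord-class].
#' @param refset a reference set from [referenceSet()] (or any named
#'   `AAStringSet` in a list with element `proteins`).
#' @param minIdentity,maxEvalue thresholds.
#' @param minCov optional coverage threshold on the shorter sequence
#'   (default 0: the screen is identity/E-value based).
#' @return hit `data.frame` as in [searchHomologs()], at most one row per
#'   query protein.
#' @export
screenProteome <- function(proteomeSet, refset, minIdentity = 30,
                           maxEvalue = 1e-6, minCov = 0) {
  if (is(proteomeSet, "GenomeRecord")) proteomeSet <- proteome(proteomeSet)
  refs <- if (is.list(refset)) refset$proteins else refset
  hits <- searchHomologs(proteomeSet, refs, minIdentity = minIdentity,
                         minCov = minCov, covMode = "shorter",
                         maxEvalue = maxEvalue)
  if (nrow(hits) == 0L) return(hits)
  .bestBySide(hits, "query_id")
}

#' Check the conserved LuxI triad (Arg24, Phe28, Trp34)
#'
#' Globally aligns a candidate AHL synthase to a reference LuxI-family
#' synthase and reads the candidate residues in the alignment columns of
#' reference positions 24, 28 and 34 (reference numbering). The verdict is
#' `pass` iff the candidate has R, F and W respectively; a gapped column
#' yields residue `"-"` and `fail`.
#'
#' @param candidate candidate protein sequence (character or `AAString`).
#' @param reference reference synthase defining the numbering frame;
#'   default: the first member of the shipped `luxI` set.
#' @param positions named integer vector of required residues at reference
#'   positions (default `c(R = 24, F = 28, W = 34)`).
#' @return list: `protein_id` (if candidate is named), `motif = "luxI_triad"`,
#'   `residues_found` (named by reference position), `verdict` (`"pass"` /
#'   `"fail"`).
#' @export
checkLuxITriad <- function(candidate, reference = NULL,
                           positions = c(R = 24L, F = 28L, W = 34L)) {
  if (is.null(reference)) reference <- referenceSet("luxI")$proteins[[1]]
  cand <- as.character(candidate)[1]
  ref <- as.character(reference)[1]
  al <- pairwiseAlignment(AAString(cand), AAString(ref), type = "global",
                          substitutionMatrix = .blosum62(),
                          gapOpening = 11, gapExtension = 1)
  ca <- strsplit(as.character(aligned(pattern(al)))[1], "")[[1]]
  ra <- strsplit(as.character(aligned(subject(al)))[1], "")[[1]]
  refpos <- cumsum(ra != "-")
  found <- vapply(positions, function(p) {
    col <- which(refpos == p & ra != "-")[1]
    if (is.na(col)) "-" else ca[col]
  }, "")
  names(found) <- as.character(positions)
  verdict <- if (identical(unname(found), names(positions))) "pass" else
    "fail"
  list(protein_id = if (!is.null(names(candidate))) names(candidate)[1] else
         NA_character_,
       motif = "luxI_triad", residues_found = found, verdict = verdict)
}

#' Spacing of the Rieske [2Fe-2S] binding site
#'
#' Locates the iron-sulfur binding motif `C-X-H-X(n)-C-X-X-H` with the gap
#' bound `n` in 13..25 (bracketing both the canonical 17-residue spacing of
#' Group II ring-hydroxylating dioxygenases and the 19-residue variant, with
#' margin) and returns the number of residues strictly between the first
#' histidine and the second cysteine. The first match (leftmost start,
#' smallest spacing at that start) is reported; additional matches are
#' noted via `message()`.
#'
#' @param proteinSeq protein sequence (character or `AAString`).
#' @param gapRange allowed spacing range (default `13:25`).
#' @return integer spacing, or `NA` if the motif is absent.
#' @examples
#' rieskeSpacing(paste0("MA", "CAH", strrep("G", 17), "CAAH", "KL"))  # 17
#' @export
rieskeSpacing <- function(proteinSeq, gapRange = 13:25) {
  s <- strsplit(as.character(proteinSeq)[1], "")[[1]]
  n <- length(s)
  matches <- integer()
  for (i in seq_len(max(0L, n - 6L - min(gapRange)))) {
    if (s[i] != "C" || i + 2L > n || s[i + 2L] != "H") next
    for (g in gapRange) {
      j <- i + 3L + g          # position of the second C
      if (j + 3L > n) break
      if (s[j] == "C" && s[j + 3L] == "H") matches <- c(matches, g)
    }
  }
  if (length(matches) == 0L) return(NA_integer_)
  if (length(matches) > 1L)
    message("multiple Rieske-site matches; reporting the first ",
            "(spacings: ", paste(matches, collapse = ", "), ")")
  matches[1]
}

#' Detect a colocalized gene cassette (e.g. ectoine ectABC)
#'
#' Screens the proteome against one reference set per cassette component and
#' asks whether at least one hit of every component falls within a single
#' window of the stated span on one replicon. The default 20-kb window
#' matches the genomic region over which the ectoine biosynthesis cassette
#' is syntenic in marine isolates.
#'
#' @param genome a [GenomeRecord-class] with CDS coordinates.
#' @param componentRefsets named list of reference sets (as from
#'   [referenceSet()]), e.g. `list(EctA = ..., EctB = ..., EctC = ...)`.
#' @param window window span in bp (default 20000).
#' @param minIdentity,maxEvalue screening thresholds.
#' @return list: `genome_id`, `components_found` (character vector),
#'   `window_span` (smallest span covering one hit of each component; `NA`
#'   when incomplete), `replicon` and `complete` (logical).
#' @export
detectCassette <- function(genome, componentRefsets, window = 20000,
                           minIdentity = 30, maxEvalue = 1e-6) {
  stopifnot(is(genome, "GenomeRecord"), length(componentRefsets) >= 1L)
  pm <- mcols(proteome(genome))
  hits <- lapply(componentRefsets, function(rs)
    screenProteome(genome, rs, minIdentity = minIdentity,
                   maxEvalue = maxEvalue))
  found <- names(componentRefsets)[vapply(hits, nrow, 0L) > 0L]
  res <- list(genome_id = genomeId(genome), components_found = found,
              window_span = NA_real_, replicon = NA_character_,
              complete = FALSE)
  if (length(found) < length(componentRefsets)) return(res)
  # per component: (replicon, midpoint) of each hit CDS
  locs <- lapply(hits, function(h) {
    ix <- match(h$query_id, names(proteome(genome)))
    data.frame(replicon = pm$replicon_id[ix],
               pos = (pm$start[ix] + pm$end[ix]) / 2)
  })
  best <- Inf
  best_rep <- NA_character_
  for (r in unique(locs[[1]]$replicon)) {
    per <- lapply(locs, function(l) sort(l$pos[l$replicon == r]))
    if (any(vapply(per, length, 0L) == 0L)) next
    # minimal span containing one position from each component
    grid <- expand.grid(lapply(per, seq_along))
    for (k in seq_len(nrow(grid))) {
      ps <- vapply(seq_along(per), function(c) per[[c]][grid[k, c]], 0)
      span <- max(ps) - min(ps)
      if (span < best) {
        best <- span
        best_rep <- r
      }
    }
  }
  if (is.finite(best)) {
    res$window_span <- best
    res$replicon <- best_rep
    res$complete <- best <= window
  }
  res
}

#' Call LuxR "solo" regulators
#'
#' A LuxR solo is a LuxR-family regulator with no AHL synthase (LuxI
#' homolog) encoded nearby. Both families are identified by homology
#' screening; a LuxR hit is a solo when no LuxI hit lies within
#' `maxGeneDistance` gene positions on the same replicon.
#'
#' @param genome a [GenomeRecord-class].
#' @param luxRSet,luxISet reference sets (defaults: shipped sets).
#' @param maxGeneDistance adjacency radius in genes (default 5).
#' @param minIdentity,maxEvalue screening thresholds.
#' @return `data.frame`: `protein_id`, `replicon_id`, `gene_order_index`,
#'   `nearest_luxI_distance` (genes; `Inf` if none on the replicon), `solo`.
#' @export
luxRSolos <- function(genome, luxRSet = referenceSet("luxR"),
                      luxISet = referenceSet("luxI"), maxGeneDistance = 5L,
                      minIdentity = 30, maxEvalue = 1e-6) {
  pm <- mcols(proteome(genome))
  rhits <- screenProteome(genome, luxRSet, minIdentity, maxEvalue)
  ihits <- screenProteome(genome, luxISet, minIdentity, maxEvalue)
  if (nrow(rhits) == 0L)
    return(data.frame(protein_id = character(), replicon_id = character(),
                      gene_order_index = integer(),
                      nearest_luxI_distance = numeric(), solo = logical()))
  loc <- function(ids) {
    ix <- match(ids, names(proteome(genome)))
    data.frame(replicon = pm$replicon_id[ix], goi = pm$gene_order_index[ix])
  }
  rl <- loc(rhits$query_id)
  il <- loc(ihits$query_id)
  nearest <- vapply(seq_len(nrow(rl)), function(k) {
    same <- il$goi[il$replicon == rl$replicon[k]]
    if (length(same) == 0L) Inf else min(abs(same - rl$goi[k]))
  }, 0)
  data.frame(protein_id = rhits$query_id, replicon_id = rl$replicon,
             gene_order_index = rl$goi, nearest_luxI_distance = nearest,
             solo = nearest > maxGeneDistance)
}
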