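#' Dinucleotide relative abundance profile of a genome
#'
#' Computes the strand-symmetrized dinucleotide signature: counts are
#' accumulated over every replicon on the forward strand and over each
#' replicon's reverse complement, with no window spanning a replicon junction
#' or the forward/reverse seam. Windows containing an ambiguous base
#' contribute nothing (they are skipped, not imputed). Frequencies are
#' counts/total; `rho*_XY = f*_XY / (f*_X f*_Y)` measures over- (>1) or
#' under-representation (<1) of each dinucleotide relative to base
#' composition, the classic genome-signature statistic.
#'
#' @param genome a [GenomeRecord-class], or a `DNAStringSet`/character vector
#'   of replicon sequences.
#' @param includePlasmids if `FALSE`, plasmid replicons are excluded.
#' @param genomeId identifier stored in the profile (default: the genome's).
#' @return a [DinucProfile-class].
#' @examples
#' p <- dinucProfile(GenomeRecord("t", c(chr = "AATT"), kind = "chromosome"))
#' rhoValues(p)[["AA"]]  # 4/3
#' @export
dinucProfile <- function(genome, includePlasmids = TRUE, genomeId = NULL) {
  if (is(genome, "GenomeRecord")) {
    if (is.null(genomeId)) genomeId <- genomeId(genome)
    reps <- replicons(genome)
    if (!includePlasmids) reps <- reps[repliconKind(genome) != "plasmid"]
  } else {
    reps <- if (is(genome, "DNAStringSet")) genome else DNAStringSet(genome)
    if (is.null(genomeId)) genomeId <- "genome"
  }
  if (length(reps) == 0L) stop("no replicons selected")
  mcols(reps) <- NULL
  both <- c(reps, reverseComplement(reps))
  di <- colSums(dinucleotideFrequency(both))       # non-ACGT windows skipped
  mono <- colSums(letterFrequency(both, .BASES))   # ambiguity codes excluded
  if (sum(di) < 1)
    stop("undefined profile: no valid (unambiguous) dinucleotide window")
  f_di <- di / sum(di)
  f_mono <- mono / sum(mono)
  expct <- f_mono[substr(.DINUCS, 1, 1)] * f_mono[substr(.DINUCS, 2, 2)]
  # 0/0 (a base absent from the genome) is defined as 0
  rho <- ifelse(expct > 0, f_di[.DINUCS] / expct, 0)
  names(rho) <- .DINUCS
  new("DinucProfile", genome_id = genomeId, mono = f_mono,
      dinuc = setNames(f_di[.DINUCS], .DINUCS), rho = rho)
}

#' Karlin genome dissimilarity delta* between two signatures
#'
#' `1000/16 * sum_XY |rho*_f(XY) - rho*_g(XY)|`: the average absolute
#' difference of dinucleotide relative abundances, on the conventional
#' x1000 reporting scale.
#'
#' @param f,g [DinucProfile-class] objects.
#' @return non-negative dissimilarity (x1000 scale).
#' @examples
#' g <- GenomeRecord("t", c(chr = "ACGTACGTAA"), kind = "chromosome")
#' deltaStar(dinucProfile(g), dinucProfile(g))  # 0
#' @export
deltaStar <- function(f, g) {
  stopifnot(is(f, "DinucProfile"), is(g, "DinucProfile"))
  rf <- rhoValues(f)[.DINUCS]
  rg <- rhoValues(g)[.DINUCS]
  1000 * mean(abs(rf - rg))
}

#' Pairwise delta* matrix for a set of genomes
#'
#' @param genomes list of [GenomeRecord-class] objects or of
#'   [DinucProfile-class] objects.
#' @param includePlasmids passed to [dinucProfile()] when genomes are given.
#' @return symmetric numeric matrix of delta* (x1000) values, zero diagonal,
#'   dimnames = genome ids in input order.
#' @export
signatureMatrix <- function(genomes, includePlasmids = TRUE) {
  profs <- lapply(genomes, function(g) {
    if (is(g, "DinucProfile")) g
    else dinucProfile(g, includePlasmids = includePlasmids)
  })
  ids <- vapply(profs, function(p) p@genome_id, "")
  n <- length(profs)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- deltaStar(profs[[i]], profs[[j]])
  }
  m
}

#' Classify a rho* value into representation classes
#'
#' The conventional bands: `rho* <= 0.55` extreme under-representation,
#' `(0.55, 0.78]` under, `(0.78, 1.23]` normal, `(1.23, 1.30]` over,
#' `> 1.30` extreme over-representation. Boundary values fall in the lower
#' class, matching the strict inequalities of the defining ranges
#' (normal: 0.78 < rho* < 1.23; extreme: rho* > 1.30 or < 0.55).
#'
#' @param rho numeric vector of rho* values (must be >= 0).
#' @return factor with levels `extreme_under`, `under`, `normal`, `over`,
#'   `extreme_over`.
#' @examples
#' classifyRho(c(1.0, 1.35, 0.5))
#' @export
classifyRho <- function(rho) {
  if (any(is.na(rho)) || any(rho < 0)) stop("rho* values must be >= 0")
  cut(rho, breaks = c(-Inf, 0.55, 0.78, 1.23, 1.30, Inf),
      labels = c("extreme_under", "under", "normal", "over", "extreme_over"),
      right = TRUE)
}
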