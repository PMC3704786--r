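# Protein similarity search on top of Biostrings local alignment.
#
# Strategy mirrors a BLASTP protocol: raw Smith-Waterman scores (BLOSUM62,
# affine gaps 11/1) are computed for every query/subject pair with
# scoreOnly=TRUE, converted to E-values with Karlin-Altschul statistics on
# the query x database search space, and only pairs passing the E-value
# threshold are re-aligned in full to obtain percent identity and coverage.

# Published gapped Karlin-Altschul parameters for BLOSUM62, gap open 11 /
# extend 1 (as used by blastp).
.KA <- list(lambda = 0.267, K = 0.041)

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

.cleanAA <- function(x, ctx = "proteome") {
  x <- if (is(x, "AAStringSet")) x else AAStringSet(x)
  mcols(x) <- NULL   # CDS metadata is irrelevant here and noisy under rep()
  chars <- Biostrings::uniqueLetters(x)
  bad <- setdiff(chars, c(.AA20, "X"))
  if (length(bad)) {
    warning("non-standard residues ", paste(bad, collapse = ""),
            " in ", ctx, ": masked to X")
    x <- AAStringSet(chartr(paste(bad, collapse = ""),
                            strrep("X", length(bad)), as.character(x)))
  }
  x
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' All-vs-all protein homology search
#'
#' Local alignment (Smith-Waterman, BLOSUM62, affine gap open 11 / extend 1)
#' of every query against every subject, with BLAST-style E-values from
#' Karlin-Altschul statistics on the effective search space (query length x
#' total subject residues). Hits failing any of the identity, coverage or
#' E-value thresholds are dropped. Percent identity is identities / aligned
#' columns (internal gaps included); coverage is the aligned span of each
#' sequence divided by its length.
#'
#' @param query,subject named `AAStringSet` (or character vectors).
#' @param minIdentity minimum percent identity (default 30).
#' @param minCov minimum coverage fraction (default 0.7).
#' @param covMode which sequence the coverage threshold applies to:
#'   `"shorter"` (default, the conventional AAI rule), `"longer"` (overlap
#'   relative to the longer sequence, the stricter pan-genome rule), or
#'   `"query"`.
#' @param maxEvalue maximum E-value (default 1e-6).
#' @return `data.frame` of hits: `query_id`, `subject_id`, `pct_identity`,
#'   `query_cov`, `subject_cov`, `score` (raw), `bitscore`, `evalue`.
#' @seealso [reciprocalBestHits()], [computeAAI()]
#' @export
searchHomologs <- function(query, subject, minIdentity = 30, minCov = 0.7,
                           covMode = c("shorter", "longer", "query"),
                           maxEvalue = 1e-6) {
  covMode <- match.arg(covMode)
  query <- .cleanAA(query, "query")
  subject <- .cleanAA(subject, "subject")
  empty <- data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), query_cov = numeric(),
                      subject_cov = numeric(), score = numeric(),
                      bitscore = numeric(), evalue = numeric())
  if (length(query) == 0L || length(subject) == 0L) return(empty)
  if (is.null(names(query)) || is.null(names(subject)))
    stop("query and subject sequences must be named")
  mat <- .blosum62()
  dbres <- sum(width(subject))
  out <- vector("list", length(query))
  for (i in seq_along(query)) {
    sc <- pairwiseAlignment(rep(query[i], length(subject)), subject,
                            type = "local", substitutionMatrix = mat,
                            gapOpening = 11, gapExtension = 1,
                            scoreOnly = TRUE)
    ev <- .KA$K * width(query)[i] * dbres * exp(-.KA$lambda * sc)
    cand <- which(ev <= maxEvalue)
    if (length(cand) == 0L) next
    al <- pairwiseAlignment(rep(query[i], length(cand)), subject[cand],
                            type = "local", substitutionMatrix = mat,
                            gapOpening = 11, gapExtension = 1)
    pidv <- pid(al, type = "PID1")
    qsp <- width(pattern(al)@range)
    ssp <- width(subject(al)@range)
    qcov <- qsp / width(query)[i]
    scov <- ssp / width(subject)[cand]
    cov <- switch(covMode,
                  shorter = ifelse(width(query)[i] <= width(subject)[cand],
                                   qcov, scov),
                  longer = ifelse(width(query)[i] >= width(subject)[cand],
                                  qcov, scov),
                  query = qcov)
    keep <- pidv >= minIdentity & cov >= minCov
    if (!any(keep)) next
    out[[i]] <- data.frame(
      query_id = names(query)[i], subject_id = names(subject)[cand][keep],
      pct_identity = pidv[keep], query_cov = qcov[keep],
      subject_cov = scov[keep], score = sc[cand][keep],
      bitscore = (.KA$lambda * sc[cand][keep] - log(.KA$K)) / log(2),
      evalue = ev[cand][keep]
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) empty else {
    rownames(res) <- NULL
    res
  }
}

.bestBySide <- function(hits, side = c("query_id", "subject_id")) {
  side <- match.arg(side)
  other <- setdiff(c("query_id", "subject_id"), side)
  ord <- order(hits[[side]], -hits$score, -hits$pct_identity, hits[[other]])
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h[[side]]), , drop = FALSE]
}

#' Reciprocal best hits between two proteomes
#'
#' `(a, b)` is retained iff `b` is `a`'s highest-scoring hit in the A-vs-B
#' search and `a` is `b`'s highest-scoring hit in the B-vs-A search. Ties on
#' raw score are broken by higher percent identity, then lexicographically
#' smaller partner id, so the result is deterministic.
#'
#' @param hitsAB hits from [searchHomologs()] with A as query.
#' @param hitsBA hits with B as query.
#' @return `data.frame` with `protein_a`, `protein_b`, `pct_identity` (mean
#'   of the two directions' identities), `score` (A-vs-B raw score).
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA) {
  empty <- data.frame(protein_a = character(), protein_b = character(),
                      pct_identity = numeric(), score = numeric())
  if (nrow(hitsAB) == 0L || nrow(hitsBA) == 0L) return(empty)
  bestAB <- .bestBySide(hitsAB, "query_id")
  bestBA <- .bestBySide(hitsBA, "query_id")
  key_ab <- paste(bestAB$query_id, bestAB$subject_id, sep = "\r")
  key_ba <- paste(bestBA$subject_id, bestBA$query_id, sep = "\r")
  m <- match(key_ab, key_ba)
  keep <- !is.na(m)
  if (!any(keep)) return(empty)
  data.frame(
    protein_a = bestAB$query_id[keep],
    protein_b = bestAB$subject_id[keep],
    pct_identity = (bestAB$pct_identity[keep] +
                    bestBA$pct_identity[m[keep]]) / 2,
    score = bestAB$score[keep]
  )
}

#' Average amino acid identity (AAI) between two genomes
#'
#' Runs the homology search in both directions under the conventional AAI
#' thresholds (30% identity, 70% coverage of the shorter sequence,
#' E <= 1e-6), takes reciprocal best hits, and averages their percent
#' identities (unweighted). AAI is symmetric in its two arguments by
#' construction.
#'
#' @param genomeA,genomeB [GenomeRecord-class] objects or named
#'   `AAStringSet` proteomes.
#' @param minIdentity,minCov,maxEvalue hit thresholds.
#' @param oneWay if `TRUE`, use A-vs-B best hits only instead of reciprocal
#'   best hits (some AAI implementations do this; not the default).
#' @return `data.frame` row: `genome_a`, `genome_b`, `n_rbh`, `aai`.
#' @examples
#' \donttest{
#' fam <- genOrthologFamily(120, 2, 0.9, seed = 1)
#' a <- setNames(fam$proteins[1], "p1"); b <- setNames(fam$proteins[2], "p1")
#' computeAAI(a, b, minCov = 0.5)
#' }
#' @export
computeAAI <- function(genomeA, genomeB, minIdentity = 30, minCov = 0.7,
                       maxEvalue = 1e-6, oneWay = FALSE) {
  pa <- if (is(genomeA, "GenomeRecord")) proteome(genomeA) else
    .cleanAA(genomeA)
  pb <- if (is(genomeB, "GenomeRecord")) proteome(genomeB) else
    .cleanAA(genomeB)
  ida <- if (is(genomeA, "GenomeRecord")) genomeId(genomeA) else "A"
  idb <- if (is(genomeB, "GenomeRecord")) genomeId(genomeB) else "B"
  if (length(pa) == 0L || length(pb) == 0L)
    stop("both proteomes must be non-empty")
  ab <- searchHomologs(pa, pb, minIdentity = minIdentity, minCov = minCov,
                       covMode = "shorter", maxEvalue = maxEvalue)
  if (oneWay) {
    best <- .bestBySide(ab, "query_id")
    if (nrow(best) == 0L)
      stop("AAI undefined for pair (", ida, ", ", idb, "): no best hits")
    return(data.frame(genome_a = ida, genome_b = idb, n_rbh = nrow(best),
                      aai = mean(best$pct_identity)))
  }
  ba <- searchHomologs(pb, pa, minIdentity = minIdentity, minCov = minCov,
                       covMode = "shorter", maxEvalue = maxEvalue)
  rbh <- reciprocalBestHits(ab, ba)
  if (nrow(rbh) == 0L)
    stop("AAI undefined for pair (", ida, ", ", idb, "): no RBH pairs")
  data.frame(genome_a = ida, genome_b = idb, n_rbh = nrow(rbh),
             aai = mean(rbh$pct_identity))
}

#' Pairwise AAI matrix for a set of genomes
#'
#' @param genomes list of [GenomeRecord-class] objects.
#' @param ... passed to [computeAAI()].
#' @return symmetric matrix of AAI percentages; diagonal 100.
#' @export
aaiMatrix <- function(genomes, ...) {
  ids <- vapply(genomes, genomeId, "")
  n <- length(genomes)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- computeAAI(genomes[[i]], genomes[[j]], ...)$aai
  }
  m
}
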