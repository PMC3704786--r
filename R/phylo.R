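#' Read an aligned protein FASTA
#'
#' @param path aligned FASTA (gaps as `-`); all rows must be equal length.
#' @return named `AAStringSet`.
#' @export
readAlignment <- function(path) {
  aln <- readAAStringSet(path)
  names(aln) <- sub("\\s.*$", "", names(aln))
  if (length(unique(width(aln))) != 1L)
    stop("alignment rows differ in length")
  if (length(aln) < 2L) stop("alignment needs >= 2 taxa")
  aln
}

.alnMatrix <- function(aln) {
  if (is(aln, "XStringSet")) {
    m <- do.call(rbind, strsplit(as.character(aln), ""))
    rownames(m) <- names(aln)
    m
  } else if (is.matrix(aln)) aln else
    do.call(rbind, strsplit(as.character(aln), ""))
}

#' Poisson-corrected distance between two aligned sequences
#'
#' With pairwise deletion: alignment columns gapped (or ambiguous, `X`/`?`)
#' in either sequence are ignored; `p` is the fraction of mismatches among
#' the remaining columns and the distance is `-ln(1 - p)` substitutions per
#' site.
#'
#' @param x,y aligned sequences (equal-length character strings or
#'   `AAString`).
#' @return the distance; `Inf` with a warning when `p >= 1`.
#' @examples
#' poissonDistance("ACDEFG", "ACDEFG")  # 0
#' @export
poissonDistance <- function(x, y) {
  a <- strsplit(as.character(x)[1], "")[[1]]
  b <- strsplit(as.character(y)[1], "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  excl <- c("-", ".", "X", "?")
  ok <- !(a %in% excl) & !(b %in% excl)
  if (!any(ok)) stop("no shared non-gap column")
  p <- mean(a[ok] != b[ok])
  if (p >= 1) {
    warning("p >= 1: infinite Poisson distance")
    return(Inf)
  }
  -log(1 - p)
}

#' Pairwise Poisson-corrected distance matrix from an alignment
#'
#' @param aln named `AAStringSet` (or character matrix) of aligned rows.
#' @param correction `"poisson"` (default) or `"p"` for the uncorrected
#'   p-distance.
#' @return symmetric numeric matrix.
#' @export
poissonDistanceMatrix <- function(aln, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  m <- .alnMatrix(aln)
  n <- nrow(m)
  ids <- rownames(m)
  excl <- c("-", ".", "X", "?")
  okm <- !(m %in% excl)
  dim(okm) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- okm[i, ] & okm[j, ]
    if (!any(ok)) stop("no shared non-gap column for pair (",
                       ids[i], ", ", ids[j], ")")
    p <- mean(m[i, ok] != m[j, ok])
    d[i, j] <- d[j, i] <- if (correction == "p") p else {
      if (p >= 1) {
        warning("p >= 1 for pair (", ids[i], ", ", ids[j],
                "): infinite distance")
        Inf
      } else -log(1 - p)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch-length
#' estimates are clamped to zero afterwards. Taxa are processed in matrix
#' order, so output is deterministic.
#'
#' @param dm symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return an [ape] `phylo` tree.
#' @export
njTree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("neighbor joining needs >= 3 taxa")
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  tr <- ape::nj(stats::as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for the neighbor-joining tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the Poisson
#' distance matrix and the NJ tree per replicate, and reports for each
#' internal edge of the full-data tree the percentage of replicates
#' containing the same bipartition. Supports are mapped onto the full-data
#' tree (set `consensusTree = TRUE` for a majority-rule consensus topology
#' instead).
#'
#' @param aln named `AAStringSet` or character matrix of aligned rows.
#' @param replicates bootstrap replicates (default 1000).
#' @param seed RNG seed governing all resampling (default 1).
#' @param correction passed to [poissonDistanceMatrix()].
#' @param consensusTree if `TRUE`, return the majority-rule consensus of the
#'   replicate trees instead of the full-data tree.
#' @return a `phylo` tree whose `node.label` holds bootstrap percentages
#'   (root label empty).
#' @export
bootstrapTree <- function(aln, replicates = 1000, seed = 1,
                          correction = "poisson", consensusTree = FALSE) {
  stopifnot(replicates >= 1)
  m <- .alnMatrix(aln)
  set.seed(seed)
  main <- njTree(poissonDistanceMatrix(m, correction = correction))
  reps <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[b]] <- njTree(poissonDistanceMatrix(m[, cols, drop = FALSE],
                                              correction = correction))
  }
  if (consensusTree) {
    cons <- ape::consensus(reps, p = 0.5)
    counts <- ape::prop.clades(cons, reps, rooted = FALSE)
    cons$node.label <- .supportLabels(counts, replicates)
    return(cons)
  }
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  main$node.label <- .supportLabels(counts, replicates)
  main
}

.supportLabels <- function(counts, replicates) {
  lab <- round(100 * counts / replicates)
  lab[is.na(lab)] <- ""
  as.character(lab)
}
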