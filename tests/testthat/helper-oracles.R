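# Independent oracles and small fixture builders used across the test files.

.AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

randomProtein <- function(len) paste(sample(.AA, len, TRUE), collapse = "")

randomDNA <- function(len, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, TRUE, prob = prob), collapse = "")
}

# Brute-force Smith-Waterman with affine gaps (Gotoh), BLOSUM62, same gap
# model as the package search (gap of length L costs open + L * ext).
# Independent of the package implementation path.
swOracle <- function(a, b, open = 11, ext = 1) {
  B62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F_ <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F_[i, j] <- max(H[i - 1, j] - open - ext, F_[i - 1, j] - ext)
      H[i, j] <- max(0, E[i, j], F_[i, j],
                     H[i - 1, j - 1] + B62[x[i - 1], y[j - 1]])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Net-charge grid scan for pI, restating the EMBOSS pKa constants
# independently of the package table.
piGridOracle <- function(seq, step = 1e-4) {
  pka <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
           H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
  s <- strsplit(seq, "")[[1]]
  n <- setNames(vapply(c("C", "D", "E", "H", "K", "R", "Y"),
                       function(a) sum(s == a), 0), NULL)
  names(n) <- c("C", "D", "E", "H", "K", "R", "Y")
  ph <- seq(0, 14, by = step)
  z <- 1 / (1 + 10^(ph - pka["Nterm"])) +
    n["H"] / (1 + 10^(ph - pka["H"])) +
    n["K"] / (1 + 10^(ph - pka["K"])) +
    n["R"] / (1 + 10^(ph - pka["R"])) -
    1 / (1 + 10^(pka["Cterm"] - ph)) -
    n["C"] / (1 + 10^(pka["C"] - ph)) -
    n["D"] / (1 + 10^(pka["D"] - ph)) -
    n["E"] / (1 + 10^(pka["E"] - ph)) -
    n["Y"] / (1 + 10^(pka["Y"] - ph))
  ph[which.min(abs(z))]
}

# Random additive 4-taxon distance matrix with a known generating split.
# Returns the matrix and the sibling pair of the internal edge.
additive4 <- function() {
  taxa <- c("A", "B", "C", "D")
  pair <- sort(sample(taxa, 2))
  rest <- setdiff(taxa, pair)
  # pendant branches a,b,c,d and internal branch e (all > 0)
  bl <- runif(5, 0.05, 1)
  d <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  pen <- setNames(bl[1:4], c(pair, rest))
  e <- bl[5]
  for (i in 1:3) for (j in (i + 1):4) {
    ti <- taxa[i]; tj <- taxa[j]
    same <- (ti %in% pair) == (tj %in% pair)
    d[ti, tj] <- d[tj, ti] <- pen[ti] + pen[tj] + if (same) 0 else e
  }
  list(d = d, pair = pair)
}

# Sibling pair across the internal edge of an unrooted 4-taxon tree,
# normalized to the side containing the alphabetically first taxon (both
# sides of the split name the same topology).
njSiblingPair <- function(tree) {
  stopifnot(length(tree$tip.label) == 4L)
  internal <- tree$edge[tree$edge[, 2] > 4L, 2]
  kids <- tree$edge[tree$edge[, 1] == internal[length(internal)] &
                      tree$edge[, 2] <= 4L, 2]
  side <- sort(tree$tip.label[kids])
  first <- sort(tree$tip.label)[1]
  if (first %in% side) side else sort(setdiff(tree$tip.label, side))
}

# Normalize a generating pair the same way for comparison.
normalizePair <- function(pair, taxa = c("A", "B", "C", "D")) {
  first <- sort(taxa)[1]
  if (first %in% pair) sort(pair) else sort(setdiff(taxa, pair))
}

# Minimal i.i.d.-composition genome for profile property tests.
randomGenome <- function(id, len = 3000, prob = NULL) {
  if (is.null(prob)) {
    prob <- runif(4, 0.5, 1.5)
    prob <- prob / sum(prob)
  }
  GenomeRecord(id, setNames(randomDNA(len, prob), paste0(id, "_chr")),
               kind = "chromosome")
}
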