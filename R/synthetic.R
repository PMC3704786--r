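# Synthetic genomes with known ground truth: first-order Markov nucleotide
# sequences with analytic dinucleotide signatures, ortholog families at
# controlled percent identity, and planted trait markers (LuxI-like triads,
# Rieske sites with chosen spacing, colocalized ectABC cassettes,
# plasmid-assigned singletons).

# Robinson-Robinson amino acid background frequencies.
.AA_BG <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
            Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
            L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
            S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

# BLOSUM62-conditional replacement distribution: P(b | a, b != a)
# proportional to bg(b) * exp(lambda * s(a, b)), lambda = 0.3176 (ungapped).
.replacementMatrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      B <- .blosum62()[.AA20, .AA20]
      w <- sweep(exp(0.3176 * B), 2, .AA_BG[.AA20], "*")
      diag(w) <- 0
      m <<- sweep(w, 1, rowSums(w), "/")
    }
    m
  }
})

.validStochastic <- function(trans) {
  is.matrix(trans) && all(dim(trans) == 4L) && all(trans >= 0) &&
    all(abs(rowSums(trans) - 1) < 1e-8)
}

#' Stationary distribution of a 4-state nucleotide Markov chain
#'
#' @param trans 4x4 row-stochastic transition matrix (rows/cols A,C,G,T).
#' @return named numeric(4) stationary probabilities.
#' @export
stationaryDistribution <- function(trans) {
  if (!.validStochastic(trans)) stop("'trans' must be 4x4 row-stochastic")
  e <- eigen(t(trans))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  setNames(v / sum(v), .BASES)
}

#' Analytic dinucleotide profile of a stationary Markov chain
#'
#' The expected strand-symmetrized signature of an infinitely long sequence
#' generated by the chain: stationary dinucleotide probabilities
#' `q(XY) = pi_X P[X,Y]` are averaged with their reverse complements, and
#' `rho*` follows from the symmetrized mono- and dinucleotide frequencies.
#' Used as ground truth for [dinucProfile()] on generated genomes.
#'
#' @param trans 4x4 row-stochastic transition matrix.
#' @param genomeId identifier stored in the profile.
#' @return a [DinucProfile-class].
#' @export
expectedDinucProfile <- function(trans, genomeId = "markov") {
  pi_ <- stationaryDistribution(trans)
  dimnames(trans) <- list(.BASES, .BASES)
  q <- sweep(trans, 1, pi_, "*")          # q[X, Y]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  f_di <- setNames(vapply(.DINUCS, function(xy) {
    x <- substr(xy, 1, 1)
    y <- substr(xy, 2, 2)
    (q[x, y] + q[comp[y], comp[x]]) / 2
  }, 0), .DINUCS)
  f_mono <- setNames((pi_ + pi_[comp[.BASES]]) / 2, .BASES)
  expct <- f_mono[substr(.DINUCS, 1, 1)] * f_mono[substr(.DINUCS, 2, 2)]
  rho <- ifelse(expct > 0, f_di / expct, 0)
  new("DinucProfile", genome_id = genomeId, mono = f_mono,
      dinuc = f_di, rho = setNames(rho, .DINUCS))
}

#' Generate a nucleotide sequence from a first-order Markov chain
#'
#' @param length sequence length in bp (>= 1000 for genome use; smaller
#'   values allowed for testing).
#' @param trans 4x4 row-stochastic transition matrix (A,C,G,T order).
#' @param init initial distribution; default: the stationary distribution.
#' @param seed optional RNG seed; `NULL` uses the current RNG state.
#' @return character string over ACGT.
#' @export
genMarkovSequence <- function(length, trans, init = NULL, seed = NULL) {
  if (!.validStochastic(trans)) stop("'trans' must be 4x4 row-stochastic")
  stopifnot(length >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- stationaryDistribution(trans)
  cum <- t(apply(trans, 1, cumsum))
  a1 <- cum[, 1]; a2 <- cum[, 2]; a3 <- cum[, 3]
  u <- runif(length)
  idx <- integer(length)
  ci <- cumsum(init)
  idx[1] <- 1L + (u[1] > ci[1]) + (u[1] > ci[2]) + (u[1] > ci[3])
  if (length > 1L) for (i in 2:length) {
    p <- idx[i - 1L]
    ui <- u[i]
    idx[i] <- 1L + (ui > a1[p]) + (ui > a2[p]) + (ui > a3[p])
  }
  paste(.BASES[idx], collapse = "")
}

#' Generate a genome replicon with analytic signature ground truth
#'
#' @inheritParams genMarkovSequence
#' @param id replicon id.
#' @return list: `seq` (character), `expected` (analytic
#'   [DinucProfile-class] of the generating chain).
#' @export
genGenomeSequence <- function(length, trans, init = NULL, seed = NULL,
                              id = "chr") {
  if (length < 1000) stop("genome length must be >= 1000 bp")
  list(seq = genMarkovSequence(length, trans, init = init, seed = seed),
       expected = expectedDinucProfile(trans, genomeId = id))
}

#' Generate an ortholog protein family at a target percent identity
#'
#' An ancestor is drawn from the Robinson-Robinson background; each copy
#' independently receives substitutions at a per-site probability solved so
#' that the expected pairwise identity between copies equals the target
#' (including the small probability that two copies substitute to the same
#' residue). Replacement residues are sampled from a BLOSUM62-conditional
#' distribution.
#'
#' @param ancestorLength protein length (aa).
#' @param nCopies number of family members.
#' @param targetIdentity expected pairwise identity between members, in
#'   (0, 1].
#' @param seed optional RNG seed.
#' @return list: `proteins` (character vector of `nCopies` sequences),
#'   `ancestor`, `target_identity`, `realized_identity` (pairwise matrix).
#' @export
genOrthologFamily <- function(ancestorLength, nCopies, targetIdentity,
                              seed = NULL) {
  stopifnot(targetIdentity > 0, targetIdentity <= 1, nCopies >= 1)
  if (!is.null(seed)) set.seed(seed)
  anc <- sample(.AA20, ancestorLength, replace = TRUE, prob = .AA_BG)
  R <- .replacementMatrix()
  # coincidence probability: two independent replacements of the same
  # ancestor residue agree
  cc <- sum(.AA_BG[.AA20] * rowSums(R^2))
  t <- targetIdentity
  m <- (1 - sqrt(max(0, 1 - (1 + cc) * (1 - t)))) / (1 + cc)
  copies <- vapply(seq_len(nCopies), function(k) {
    s <- anc
    hit <- runif(ancestorLength) < m
    if (any(hit)) s[hit] <- vapply(s[hit], function(a)
      sample(.AA20, 1L, prob = R[a, ]), "")
    paste(s, collapse = "")
  }, "")
  ident <- diag(1, nCopies)
  if (nCopies >= 2L) {
    sm <- do.call(rbind, strsplit(copies, ""))
    for (i in 1:(nCopies - 1L)) for (j in (i + 1L):nCopies)
      ident[i, j] <- ident[j, i] <- mean(sm[i, ] == sm[j, ])
  }
  list(proteins = copies, ancestor = paste(anc, collapse = ""),
       target_identity = targetIdentity, realized_identity = ident,
       substitution_rate = m)
}

# Mutate a protein towards a target identity with the reference, optionally
# protecting positions (kept intact) or forcing positions to given residues.
.mutateFrom <- function(refSeq, targetIdentity, protect = integer(),
                        force = NULL) {
  s <- strsplit(refSeq, "")[[1]]
  R <- .replacementMatrix()
  m <- 1 - targetIdentity
  idx <- setdiff(seq_along(s), protect)
  hit <- idx[runif(length(idx)) < m]
  if (length(hit)) s[hit] <- vapply(s[hit], function(a)
    sample(.AA20, 1L, prob = R[a, ]), "")
  if (!is.null(force)) for (p in names(force)) s[as.integer(p)] <- force[[p]]
  paste(s, collapse = "")
}

#' Generate a LuxI-like AHL synthase candidate
#'
#' Mutates a reference synthase to a target overall identity while keeping
#' (or deliberately breaking) the absolutely conserved Arg24/Phe28/Trp34
#' triad.
#'
#' @param targetIdentity identity to the reference (default 0.6).
#' @param triadIntact keep the triad (default `TRUE`); if `FALSE`, position
#'   28 is substituted to alanine.
#' @param reference reference synthase (default: first shipped luxI member).
#' @param seed optional RNG seed.
#' @return protein sequence (character).
#' @export
genLuxILike <- function(targetIdentity = 0.6, triadIntact = TRUE,
                        reference = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference))
    reference <- as.character(referenceSet("luxI")$proteins[[1]])
  protect <- c(24L, 28L, 34L)
  force <- if (triadIntact) NULL else c("28" = "A")
  .mutateFrom(as.character(reference), targetIdentity, protect = protect,
              force = force)
}

#' Generate a ring-hydroxylating dioxygenase-like protein with a chosen
#' Rieske spacing
#'
#' Mutates a shipped ARDO reference (which carries a canonical
#' `C-X-H-X(17)-C-X-X-H` site) to a target identity while keeping the
#' Rieske residues fixed, then repositions the second Cys/His pair to
#' produce the requested His-Cys spacing. Replacement residues never
#' introduce C or H, so the planted site remains the unique motif match and
#' the protein still screens as an ARDO homolog.
#'
#' @param spacing residues between the first His and the second Cys
#'   (default 17, the canonical Group II value; 19 reproduces the variant
#'   architecture).
#' @param targetIdentity identity to the reference (default 0.7).
#' @param seed optional RNG seed.
#' @return protein sequence (character).
#' @export
genArdoLike <- function(spacing = 17, targetIdentity = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- as.character(referenceSet("ardo")$proteins[[1]])
  s <- strsplit(ref, "")[[1]]
  # reference site: C60 X H62 X(17) C80 X X H83
  c1 <- 60L; h1 <- 62L; c2 <- 80L; h2 <- 83L
  motif <- c(c1, h1, c2, h2)
  pool <- setdiff(.AA20, c("C", "H"))
  bgp <- .AA_BG[pool] / sum(.AA_BG[pool])
  m <- 1 - targetIdentity
  idx <- setdiff(seq_along(s), motif)
  hit <- idx[runif(length(idx)) < m]
  if (length(hit)) s[hit] <- sample(pool, length(hit), replace = TRUE,
                                    prob = bgp)
  if (spacing != 17L) {
    shift <- spacing - 17L
    if (c2 + shift + 3L > length(s) || spacing < 1L)
      stop("spacing out of range for the reference scaffold")
    s[c(c2, h2)] <- sample(pool, 2L, replace = TRUE, prob = bgp)
    s[c2 + shift] <- "C"
    s[h2 + shift] <- "H"
  }
  paste(s, collapse = "")
}

#' Generate a protein with a planted Rieske [2Fe-2S] site
#'
#' Flank and spacer residues are drawn from the background excluding C and
#' H, so the planted `C-X-H-X(n)-C-X-X-H` site is the unique match.
#'
#' @param spacing residues between the first His and second Cys (e.g. 17 or
#'   19).
#' @param length total protein length (default 150).
#' @param at 1-based position of the first cysteine (default 40).
#' @param seed optional RNG seed.
#' @return protein sequence (character).
#' @export
genRieskeProtein <- function(spacing = 17, length = 150, at = 40,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(at + 6 + spacing <= length, at >= 1)
  pool <- setdiff(.AA20, c("C", "H"))
  bg <- .AA_BG[pool] / sum(.AA_BG[pool])
  s <- sample(pool, length, replace = TRUE, prob = bg)
  s[at] <- "C"
  s[at + 2L] <- "H"
  s[at + 3L + spacing] <- "C"
  s[at + 6L + spacing] <- "H"
  paste(s, collapse = "")
}
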