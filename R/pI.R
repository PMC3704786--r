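# Protein isoelectric point from Henderson-Hasselbalch charge balance.
#
# pKa tables, indexed by ionizable group. "emboss" is the default set (the
# values used by the EMBOSS iep tool); "sillero" is offered as an
# alternative, since different published tables shift absolute pI values by
# up to ~0.2 units.
.PKA_TABLES <- list(
  emboss = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
             H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
  sillero = c(Nterm = 8.2, Cterm = 3.2, C = 9.0, D = 4.0, E = 4.5,
              H = 6.4, K = 10.4, R = 12.0, Y = 10.0)
)

.ACIDIC <- c("Cterm", "C", "D", "E", "Y")
.BASIC <- c("Nterm", "H", "K", "R")

# Net charge at pH for residue counts `cnt` (named incl. Nterm/Cterm).
.netCharge <- function(pH, cnt, pka) {
  zb <- vapply(.BASIC, function(g)
    cnt[[g]] / (1 + 10^(pH - pka[[g]])), numeric(length(pH)))
  za <- vapply(.ACIDIC, function(g)
    cnt[[g]] / (1 + 10^(pka[[g]] - pH)), numeric(length(pH)))
  if (length(pH) == 1L) sum(zb) - sum(za) else rowSums(zb) - rowSums(za)
}

.ionizableCounts <- function(seq) {
  s <- strsplit(toupper(as.character(seq)[1]), "")[[1]]
  s <- s[s %in% .AA20]          # X and other ambiguity codes carry no charge
  if (length(s) == 0L) return(NULL)
  cnt <- as.list(table(factor(s, levels = .AA20)))
  c(list(Nterm = 1L, Cterm = 1L),
    cnt[c("C", "D", "E", "H", "K", "R", "Y")])
}

#' Isoelectric point of a protein
#'
#' Solves `Z(pH) = 0` where the net charge sums Henderson-Hasselbalch terms
#' over the N-terminus, C-terminus and the ionizable side chains (D, E, C,
#' Y, H, K, R) with a fixed published pKa table. `Z` is strictly decreasing
#' in pH, so the root is found by bisection on [0, 14].
#'
#' @param proteinSeq protein sequence; `X` and other ambiguity codes are
#'   ignored for charge.
#' @param pkaTable `"emboss"` (default) or `"sillero"`.
#' @param tol bisection tolerance in pH units (default 0.001).
#' @return the pI.
#' @examples
#' isoelectricPoint("KKKKK") > 9
#' isoelectricPoint("DDDDD") < 4.5
#' @export
isoelectricPoint <- function(proteinSeq, pkaTable = c("emboss", "sillero"),
                             tol = 0.001) {
  pka <- .PKA_TABLES[[match.arg(pkaTable)]]
  cnt <- .ionizableCounts(proteinSeq)
  if (is.null(cnt))
    stop("pI undefined: no residues with ionizable groups")
  lo <- 0
  hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.netCharge(mid, cnt, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Median isoelectric point of a proteome
#'
#' @param proteomeSet named `AAStringSet`, character vector, or a
#'   [GenomeRecord-class].
#' @param pkaTable passed to [isoelectricPoint()].
#' @return median of the per-protein pI values (proteins with no ionizable
#'   group are dropped with a warning).
#' @export
medianProteomePI <- function(proteomeSet, pkaTable = "emboss") {
  if (is(proteomeSet, "GenomeRecord")) proteomeSet <- proteome(proteomeSet)
  seqs <- as.character(proteomeSet)
  pis <- vapply(seqs, function(s)
    tryCatch(isoelectricPoint(s, pkaTable = pkaTable),
             error = function(e) NA_real_), 0)
  if (anyNA(pis)) warning(sum(is.na(pis)), " protein(s) with undefined pI")
  pis <- unname(pis[!is.na(pis)])
  if (length(pis) == 0L) stop("no protein with a defined pI")
  median(pis)
}
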