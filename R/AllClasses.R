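#' GenomeRecord: a multi-replicon bacterial genome with its proteome
#'
#' Container for one genome assembly: nucleotide replicons (chromosome,
#' plasmids and/or contigs) as a [Biostrings::DNAStringSet] whose `mcols()`
#' carry the replicon `kind`, and the annotated proteome as a
#' [Biostrings::AAStringSet] whose `mcols()` record, for every CDS, the
#' replicon of origin, the 0-based gene order index along that replicon, the
#' 1-based nucleotide span and the strand.
#'
#' @slot id single genome identifier.
#' @slot replicons `DNAStringSet`, names are replicon ids; `mcols()$kind` is
#'   one of `"chromosome"`, `"plasmid"`, `"contig"`.
#' @slot proteome `AAStringSet`, names are protein ids; `mcols()` columns
#'   `replicon_id`, `gene_order_index`, `start`, `end`, `strand`.
#'
#' @seealso [readGenome()], [gcContent()], [dinucProfile()], [buildScenario()]
#' @export
setClass("GenomeRecord",
  representation(
    id = "character",
    replicons = "DNAStringSet",
    proteome = "AAStringSet"
  )
)

.REPLICON_KINDS <- c("chromosome", "plasmid", "contig")

setValidity("GenomeRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  rn <- names(object@replicons)
  if (length(object@replicons) > 0L) {
    if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn)))
      msg <- c(msg, "replicons must have unique non-empty names")
    kind <- mcols(object@replicons)$kind
    if (is.null(kind) || !all(kind %in% .REPLICON_KINDS))
      msg <- c(msg, "mcols(replicons)$kind must be chromosome/plasmid/contig")
  }
  if (length(object@proteome) > 0L) {
    pm <- mcols(object@proteome)
    need <- c("replicon_id", "gene_order_index", "start", "end", "strand")
    if (is.null(pm) || !all(need %in% colnames(pm))) {
      msg <- c(msg, paste("mcols(proteome) must have columns:",
                          paste(need, collapse = ", ")))
    } else {
      if (!all(pm$replicon_id %in% rn))
        msg <- c(msg, "every proteome replicon_id must name a replicon")
      if (any(width(object@proteome) == 0L))
        msg <- c(msg, "protein sequences must be non-empty")
      idx <- split(pm$gene_order_index, pm$replicon_id)
      if (any(vapply(idx, anyDuplicated, 0L) > 0L))
        msg <- c(msg, "gene_order_index must be unique within a replicon")
    }
    pn <- names(object@proteome)
    if (is.null(pn) || anyDuplicated(pn))
      msg <- c(msg, "protein ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeRecord
#'
#' @param id genome identifier.
#' @param replicons named `DNAStringSet` (or named character vector of
#'   nucleotide sequences).
#' @param kind character vector of replicon kinds (`"chromosome"`,
#'   `"plasmid"`, `"contig"`), recycled; defaults to `"contig"`.
#' @param proteome named `AAStringSet` (or named character vector); may be
#'   empty.
#' @param proteinInfo `data.frame` with one row per protein: `replicon_id`,
#'   `gene_order_index`, `start`, `end`, `strand`. If omitted for a non-empty
#'   proteome, all proteins are laid out in input order on the first replicon
#'   with back-to-back dummy coordinates.
#' @return a validated [GenomeRecord-class] object.
#' @examples
#' g <- GenomeRecord("toy", c(chr = "ATGCATGC"), kind = "chromosome")
#' gcContent(g)
#' @export
GenomeRecord <- function(id, replicons, kind = "contig",
                         proteome = AAStringSet(), proteinInfo = NULL) {
  if (!is(replicons, "DNAStringSet")) replicons <- DNAStringSet(replicons)
  mcols(replicons)$kind <- rep_len(kind, length(replicons))
  if (!is(proteome, "AAStringSet")) proteome <- AAStringSet(proteome)
  if (length(proteome) > 0L) {
    if (is.null(proteinInfo)) {
      len_nt <- 3L * (width(proteome) + 1L)
      end <- cumsum(len_nt)
      proteinInfo <- data.frame(
        replicon_id = names(replicons)[1L],
        gene_order_index = seq_along(proteome) - 1L,
        start = end - len_nt + 1L, end = end, strand = "+"
      )
    }
    proteinInfo$gene_order_index <- as.integer(proteinInfo$gene_order_index)
    proteinInfo$start <- as.integer(proteinInfo$start)
    proteinInfo$end <- as.integer(proteinInfo$end)
    mcols(proteome) <- DataFrame(proteinInfo)
  }
  new("GenomeRecord", id = id, replicons = replicons, proteome = proteome)
}

#' @describeIn GenomeRecord genome identifier accessor.
#' @param x a `GenomeRecord`.
#' @export
genomeId <- function(x) x@id

#' @describeIn GenomeRecord replicon accessor (`DNAStringSet` with
#'   `mcols()$kind`).
#' @export
replicons <- function(x) x@replicons

#' @describeIn GenomeRecord proteome accessor (`AAStringSet` with CDS
#'   metadata in `mcols()`).
#' @export
proteome <- function(x) x@proteome

#' @describeIn GenomeRecord replicon kinds, named by replicon id.
#' @export
repliconKind <- function(x) {
  setNames(as.character(mcols(x@replicons)$kind), names(x@replicons))
}

setMethod("show", "GenomeRecord", function(object) {
  k <- repliconKind(object)
  cat("GenomeRecord '", object@id, "': ",
      length(object@replicons), " replicon(s) (",
      paste(sprintf("%d %s", tabulate(factor(k, .REPLICON_KINDS), 3L)[
        tabulate(factor(k, .REPLICON_KINDS), 3L) > 0],
        .REPLICON_KINDS[tabulate(factor(k, .REPLICON_KINDS), 3L) > 0]),
        collapse = ", "),
      "), ", sum(width(object@replicons)), " bp, ",
      length(object@proteome), " proteins\n", sep = "")
})

#' DinucProfile: strand-symmetrized dinucleotide signature of one genome
#'
#' Mononucleotide frequencies `f*_X`, dinucleotide frequencies `f*_XY` and
#' relative abundances `rho*_XY = f*_XY / (f*_X f*_Y)`, all computed on the
#' sequence concatenated with its reverse complement (strand symmetrization),
#' so that `rho*_XY == rho*_revcomp(XY)` by construction.
#'
#' @slot genome_id genome identifier.
#' @slot mono named numeric(4), symmetrized mononucleotide frequencies
#'   (sum to 1).
#' @slot dinuc named numeric(16), symmetrized dinucleotide frequencies
#'   (sum to 1).
#' @slot rho named numeric(16), relative abundances.
#' @seealso [dinucProfile()], [deltaStar()], [classifyRho()]
#' @export
setClass("DinucProfile",
  representation(
    genome_id = "character",
    mono = "numeric",
    dinuc = "numeric",
    rho = "numeric"
  )
)

.BASES <- c("A", "C", "G", "T")
.DINUCS <- as.vector(outer(.BASES, .BASES, paste0))  # column-major: AA,CA,...

setValidity("DinucProfile", function(object) {
  msg <- character()
  if (!setequal(names(object@mono), .BASES))
    msg <- c(msg, "mono must be named by A,C,G,T")
  if (!setequal(names(object@dinuc), .DINUCS) ||
      !setequal(names(object@rho), .DINUCS))
    msg <- c(msg, "dinuc and rho must be named by the 16 dinucleotides")
  if (abs(sum(object@mono) - 1) > 1e-9)
    msg <- c(msg, "mono frequencies must sum to 1")
  if (abs(sum(object@dinuc) - 1) > 1e-9)
    msg <- c(msg, "dinuc frequencies must sum to 1")
  ok <- object@mono[substr(names(object@rho), 1, 1)] *
    object@mono[substr(names(object@rho), 2, 2)] > 0
  expct <- object@dinuc[names(object@rho)[ok]] /
    (object@mono[substr(names(object@rho)[ok], 1, 1)] *
     object@mono[substr(names(object@rho)[ok], 2, 2)])
  if (any(abs(object@rho[names(object@rho)[ok]] - expct) > 1e-9))
    msg <- c(msg, "rho must equal dinuc/(mono*mono) where defined")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DinucProfile", function(object) {
  cat("DinucProfile for '", object@genome_id, "'\n", sep = "")
  print(round(object@rho[sort(names(object@rho))], 3))
})

#' @describeIn DinucProfile the 16 `rho*` values, named by dinucleotide.
#' @param x a `DinucProfile`.
#' @export
rhoValues <- function(x) x@rho

#' @describeIn DinucProfile symmetrized mononucleotide frequencies.
#' @export
monoFreq <- function(x) x@mono

#' @describeIn DinucProfile symmetrized dinucleotide frequencies.
#' @export
dinucFreq <- function(x) x@dinuc
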