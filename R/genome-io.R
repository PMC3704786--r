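#' Read a genome assembly from FASTA or GenBank
#'
#' For FASTA input, every record becomes a replicon of kind `"contig"` and
#' the proteome is empty unless a companion protein FASTA is supplied via
#' `proteinPath` (in which case all proteins are attached to the first
#' replicon in file order). For GenBank input see [readGenBank()]: replicon
#' kinds are inferred and the proteome is populated from CDS features.
#'
#' @param path path to the assembly file.
#' @param format `"fasta"` or `"genbank"`; default guessed from the file
#'   extension (`.gb`, `.gbk`, `.gbff` mean GenBank).
#' @param genomeId genome identifier; default: basename without extension.
#' @param proteinPath optional protein FASTA accompanying a FASTA assembly.
#' @return a [GenomeRecord-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr1", "ATGCATGCAT"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path, format = c("auto", "fasta", "genbank"),
                       genomeId = NULL, proteinPath = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|gbff)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  if (format == "genbank") return(readGenBank(path, genomeId = genomeId))
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(genomeId)) genomeId <- sub("\\.[^.]*$", "", basename(path))
  reps <- readDNAStringSet(path)
  names(reps) <- sub("\\s.*$", "", names(reps))
  prot <- if (is.null(proteinPath)) AAStringSet() else {
    p <- readAAStringSet(proteinPath)
    names(p) <- sub("\\s.*$", "", names(p))
    p
  }
  GenomeRecord(genomeId, reps, kind = "contig", proteome = prot)
}

#' GC content of a genome
#'
#' Percentage `100 * (G + C) / (A + C + G + T)` summed over replicons.
#' `N` and other ambiguity codes are excluded from both numerator and
#' denominator, as the signature statistics in this package are defined over
#' the unambiguous alphabet only.
#'
#' @param genome a [GenomeRecord-class].
#' @param includePlasmids if `FALSE`, plasmid replicons are excluded (the
#'   chromosome-only figure that some genome reports quote).
#' @return GC percentage (0--100).
#' @examples
#' gcContent(GenomeRecord("g", c(chr = "GGCC"), kind = "chromosome"))  # 100
#' @export
gcContent <- function(genome, includePlasmids = TRUE) {
  stopifnot(is(genome, "GenomeRecord"))
  reps <- replicons(genome)
  if (!includePlasmids) reps <- reps[repliconKind(genome) != "plasmid"]
  if (length(reps) == 0L) stop("no replicons selected")
  cnt <- colSums(letterFrequency(reps, .BASES))
  if (sum(cnt) == 0L)
    stop("GC content undefined: no unambiguous (A/C/G/T) bases")
  unname(100 * (cnt[["G"]] + cnt[["C"]]) / sum(cnt))
}

#' Per-genome summary statistics
#'
#' @param genomes a `GenomeRecord` or list of them.
#' @return `data.frame` with one row per genome: id, number of replicons,
#'   total size (bp), GC% (all replicons), chromosome-only GC% (`NA` when no
#'   replicon is labelled chromosome), and proteome size.
#' @export
genomeStats <- function(genomes) {
  if (is(genomes, "GenomeRecord")) genomes <- list(genomes)
  do.call(rbind, lapply(genomes, function(g) {
    has_chr <- any(repliconKind(g) == "chromosome")
    data.frame(
      genome_id = genomeId(g),
      n_replicons = length(replicons(g)),
      size_bp = sum(width(replicons(g))),
      gc_pct = gcContent(g),
      gc_pct_chromosome = if (has_chr) {
        gc <- gcContent(GenomeRecord(genomeId(g),
          replicons(g)[repliconKind(g) == "chromosome"], kind = "chromosome"))
        gc
      } else NA_real_,
      n_proteins = length(proteome(g))
    )
  }))
}

#' Write a genome's proteome as protein FASTA
#'
#' @param genome a [GenomeRecord-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProteome <- function(genome, path) {
  stopifnot(is(genome, "GenomeRecord"))
  writeXStringSet(proteome(genome), path)
  invisible(path)
}
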