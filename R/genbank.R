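# Minimal GenBank flat-file I/O: enough of the format to round-trip the
# multi-replicon genomes this package works with (LOCUS, DEFINITION, source
# /organism + /plasmid, CDS with simple or complement() location, /locus_tag,
# /translation, /pseudo, ORIGIN). Compound join() locations and other feature
# types are not modelled.

.gbWrap <- function(txt, first_indent, indent, width = 79L) {
  avail1 <- width - nchar(first_indent)
  avail <- width - nchar(indent)
  out <- character()
  pos <- 1L
  n <- nchar(txt)
  take <- min(avail1, n)
  out <- substr(txt, 1L, take)
  pos <- take + 1L
  while (pos <= n) {
    take <- min(avail, n - pos + 1L)
    out <- c(out, substr(txt, pos, pos + take - 1L))
    pos <- pos + take
  }
  paste0(c(first_indent, rep(indent, length(out) - 1L)), out)
}

.gbQual <- function(name, value = NULL, quote = TRUE) {
  ind <- strrep(" ", 21L)
  if (is.null(value)) return(paste0(ind, "/", name))
  v <- if (quote) paste0("\"", value, "\"") else as.character(value)
  .gbWrap(paste0("/", name, "=", v), ind, ind)
}

#' Write a GenomeRecord as a GenBank flat file
#'
#' Emits one GenBank record per replicon, with a `source` feature (carrying a
#' `/plasmid` qualifier for plasmid replicons) and one `CDS` feature per
#' protein, including its `/translation`. Chromosome records are flagged as
#' such in the DEFINITION line so that [readGenome()] recovers the replicon
#' kind.
#'
#' @param genome a [GenomeRecord-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readGenome()]
#' @export
writeGenBank <- function(genome, path) {
  stopifnot(is(genome, "GenomeRecord"))
  con <- file(path, "w")
  on.exit(close(con))
  pm <- mcols(proteome(genome))
  kinds <- repliconKind(genome)
  for (r in names(replicons(genome))) {
    seq <- as.character(replicons(genome)[[r]])
    len <- nchar(seq)
    kind <- kinds[[r]]
    lines <- sprintf("LOCUS       %-16s %d bp    DNA     linear   BCT",
                     r, len)
    defn <- sprintf("%s %s %s.", genome@id,
                    switch(kind, chromosome = "chromosome",
                           plasmid = "plasmid", contig = "contig"), r)
    lines <- c(lines, paste0("DEFINITION  ", defn))
    lines <- c(lines, "FEATURES             Location/Qualifiers")
    lines <- c(lines, sprintf("     source          1..%d", len))
    lines <- c(lines, .gbQual("organism", genome@id))
    if (kind == "plasmid") lines <- c(lines, .gbQual("plasmid", r))
    if (length(proteome(genome)) > 0L) {
      sel <- which(pm$replicon_id == r)
      sel <- sel[order(pm$gene_order_index[sel])]
      for (i in sel) {
        loc <- sprintf("%d..%d", pm$start[i], pm$end[i])
        if (pm$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
        lines <- c(lines, sprintf("     CDS             %s", loc))
        lines <- c(lines, .gbQual("locus_tag", names(proteome(genome))[i]))
        lines <- c(lines,
                   .gbQual("translation", as.character(proteome(genome)[[i]])))
      }
    }
    lines <- c(lines, "ORIGIN")
    starts <- seq(1L, len, by = 60L)
    for (s in starts) {
      chunk <- substr(seq, s, min(s + 59L, len))
      tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      lines <- c(lines, sprintf("%9d %s", s,
                                paste(tolower(tens), collapse = " ")))
    }
    lines <- c(lines, "//")
    writeLines(lines, con)
  }
  invisible(path)
}

# Parse one GenBank record (character vector of lines, LOCUS..//-exclusive)
.gbParseRecord <- function(lines, path) {
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) != 1L)
    stop("malformed GenBank record (no LOCUS line) in ", path)
  toks <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]]
  rid <- toks[1]
  defn <- paste(trimws(sub("^DEFINITION", "", grep("^DEFINITION", lines,
                                                   value = TRUE))),
                collapse = " ")
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) != 1L)
    stop("malformed GenBank record '", rid, "' (no ORIGIN) in ", path)
  seq_lines <- lines[(ostart + 1L):length(lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feats <- list()
  if (length(fstart) == 1L && ostart > fstart + 1L) {
    flines <- lines[(fstart + 1L):(ostart - 1L)]
    key_idx <- grep("^     \\S", flines)
    bounds <- c(key_idx, length(flines) + 1L)
    for (k in seq_along(key_idx)) {
      block <- flines[key_idx[k]:(bounds[k + 1L] - 1L)]
      key <- sub("^\\s*(\\S+)\\s.*$", "\\1", block[1])
      loc <- trimws(sub("^\\s*\\S+\\s+", "", block[1]))
      # continuation lines of the location (rare here) vs qualifiers
      rest <- block[-1]
      qstart <- grep("^\\s+/", rest)
      if (length(qstart) && qstart[1] > 1L)
        loc <- paste0(loc, paste(trimws(rest[seq_len(qstart[1] - 1L)]),
                                 collapse = ""))
      quals <- list()
      if (length(qstart)) {
        qb <- c(qstart, length(rest) + 1L)
        for (q in seq_along(qstart)) {
          qtxt <- paste(trimws(rest[qstart[q]:(qb[q + 1L] - 1L)]),
                        collapse = "")
          qtxt <- sub("^/", "", qtxt)
          if (grepl("=", qtxt)) {
            qname <- sub("=.*$", "", qtxt)
            qval <- sub("^[^=]*=", "", qtxt)
            qval <- gsub("^\"|\"$", "", qval)
          } else {
            qname <- qtxt
            qval <- TRUE
          }
          quals[[qname]] <- qval
        }
      }
      feats[[length(feats) + 1L]] <- list(key = key, loc = loc, quals = quals)
    }
  }
  list(id = rid, definition = defn, seq = seq, features = feats)
}

.gbLocation <- function(loc, rid, path) {
  strand <- "+"
  x <- loc
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  x <- gsub("[<>]", "", x)
  if (!grepl("^\\d+\\.\\.\\d+$", x))
    stop("unsupported CDS location '", loc, "' on record '", rid,
         "' in ", path)
  se <- as.integer(strsplit(x, "\\.\\.")[[1]])
  list(start = se[1], end = se[2], strand = strand)
}

#' Read a GenBank flat file into a GenomeRecord
#'
#' All records in the file become replicons of one genome. Replicon kind is
#' inferred as in draft/complete bacterial assemblies: a `/plasmid` qualifier
#' on the `source` feature marks a plasmid, a DEFINITION mentioning
#' "chromosome" marks the chromosome, anything else is a contig. CDS features
#' populate the proteome in feature order; a CDS without `/translation` is
#' translated in frame from its coordinates, and `/pseudo` CDS are skipped
#' with a warning.
#'
#' @param path path to a GenBank flat file.
#' @param genomeId genome identifier; default: basename of `path` without
#'   extension.
#' @return a [GenomeRecord-class].
#' @export
readGenBank <- function(path, genomeId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  ends <- grep("^//", lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (length(ends) == 0L) stop("no GenBank record terminator (//) in ", path)
  if (is.null(genomeId)) genomeId <- sub("\\.[^.]*$", "", basename(path))

  rep_seqs <- character()
  rep_kind <- character()
  prot_seq <- character()
  info <- list()
  for (k in seq_along(ends)) {
    rec <- .gbParseRecord(lines[starts[k]:(ends[k] - 1L)], path)
    kind <- "contig"
    src <- Filter(function(f) f$key == "source", rec$features)
    if (length(src) && !is.null(src[[1]]$quals$plasmid)) {
      kind <- "plasmid"
    } else if (grepl("chromosome", rec$definition, ignore.case = TRUE)) {
      kind <- "chromosome"
    }
    rep_seqs[rec$id] <- rec$seq
    rep_kind[rec$id] <- kind
    cds <- Filter(function(f) f$key == "CDS", rec$features)
    goi <- 0L
    for (f in cds) {
      if (isTRUE(f$quals$pseudo)) {
        warning("skipping pseudo CDS at ", f$loc, " on record '", rec$id, "'")
        next
      }
      loc <- .gbLocation(f$loc, rec$id, path)
      pid <- f$quals$locus_tag
      if (is.null(pid)) pid <- sprintf("%s_cds%04d", rec$id, goi + 1L)
      aa <- f$quals$translation
      if (is.null(aa)) {
        nt <- DNAString(substr(rec$seq, loc$start, loc$end))
        if (loc$strand == "-") nt <- reverseComplement(nt)
        aa <- sub("\\*$", "",
                  as.character(suppressWarnings(
                    translate(nt, if.fuzzy.codon = "X"))))
      }
      prot_seq[pid] <- aa
      info[[length(info) + 1L]] <- data.frame(
        replicon_id = rec$id, gene_order_index = goi,
        start = loc$start, end = loc$end, strand = loc$strand
      )
      goi <- goi + 1L
    }
  }
  GenomeRecord(genomeId, DNAStringSet(rep_seqs), kind = rep_kind,
               proteome = AAStringSet(prot_seq),
               proteinInfo = if (length(info)) do.call(rbind, info) else NULL)
}
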