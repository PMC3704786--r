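test_that("FASTA assemblies load as contig replicons with empty proteome", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chr1 some description", paste(rep("ACGT", 250),
                                               collapse = "")), fa)
  g <- readGenome(fa)
  expect_s4_class(g, "GenomeRecord")
  expect_length(replicons(g), 1L)
  expect_equal(unname(Biostrings::width(replicons(g))), 1000L)
  expect_equal(unname(repliconKind(g)), "contig")
  expect_length(proteome(g), 0L)
})

test_that("GC content matches hand-computed values and ignores N", {
  expect_equal(gcContent(GenomeRecord("g", c(c = "GGCC"))), 100)
  expect_equal(gcContent(GenomeRecord("g", c(c = "ATGC"))), 50)
  expect_equal(gcContent(GenomeRecord("g", c(c = "ATGCN"))), 50)
  expect_error(gcContent(GenomeRecord("g", c(c = "NNNN"))), "undefined")
})

test_that("GC content is invariant under reverse complement", {
  set.seed(41)
  for (i in 1:5) {
    s <- randomDNA(500)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(gcContent(GenomeRecord("f", c(c = s))),
                 gcContent(GenomeRecord("r", c(c = rc))))
  }
})

test_that("GenBank round-trip preserves replicons, kinds, CDS and proteome", {
  set.seed(7)
  spec <- scenarioSpec(genomes = "gA", nCoreFamilies = 0, nSingletons = 4,
                       plasmids = list(gA = list(length = 20000,
                                                 singletonFraction = 0.5)),
                       genomeLength = 30000, seed = 7)
  g <- buildScenario(spec)$genomes[[1]]
  f <- withr::local_tempfile(fileext = ".gbk")
  writeGenBank(g, f)
  g2 <- readGenome(f, format = "genbank", genomeId = genomeId(g))
  expect_identical(as.character(replicons(g)), as.character(replicons(g2)))
  expect_identical(repliconKind(g), repliconKind(g2))
  expect_identical(as.character(proteome(g)), as.character(proteome(g2)))
  m1 <- as.data.frame(S4Vectors::mcols(proteome(g)))
  m2 <- as.data.frame(S4Vectors::mcols(proteome(g2)))
  expect_equal(m1[order(rownames(m1)), ], m2[order(rownames(m2)), ],
               ignore_attr = TRUE)
})

test_that("CDS without translation is translated in frame; pseudo skipped", {
  gb <- withr::local_tempfile(fileext = ".gbk")
  # ATG AAA TGG TAA -> MKW
  writeLines(c(
    "LOCUS       r1 24 bp    DNA     linear   BCT",
    "DEFINITION  toy chromosome r1.",
    "FEATURES             Location/Qualifiers",
    "     source          1..24",
    "     CDS             1..12",
    "                     /locus_tag=\"t1\"",
    "     CDS             13..24",
    "                     /locus_tag=\"t2\"",
    "                     /pseudo",
    "ORIGIN",
    "        1 atgaaatggt aaatgaaata ggca",
    "//"), gb)
  expect_warning(g <- readGenBank(gb), "pseudo")
  expect_length(proteome(g), 1L)
  expect_equal(as.character(proteome(g)[["t1"]]), "MKW")
})

test_that("proteome extraction count equals non-pseudo CDS count and order", {
  sc <- buildScenario(scenarioSpec(genomes = "gB", nCoreFamilies = 3,
                                   nSingletons = 2, seed = 11))
  g <- sc$genomes[[1]]
  f <- withr::local_tempfile(fileext = ".gbk")
  writeGenBank(g, f)
  n_cds <- sum(grepl("^     CDS ", readLines(f)))
  g2 <- readGenBank(f)
  expect_equal(length(proteome(g2)), n_cds)
  pm <- S4Vectors::mcols(proteome(g2))
  expect_equal(sort(pm$gene_order_index), seq_len(n_cds) - 1L)
})

test_that("genome validity is enforced", {
  expect_error(GenomeRecord("g", c(r = "ACGT"), proteome = c(p1 = "MK"),
                            proteinInfo = data.frame(
                              replicon_id = "nope", gene_order_index = 0L,
                              start = 1L, end = 9L, strand = "+")),
               "replicon")
})
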