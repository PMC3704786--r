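scenario3 <- function(seed) {
  buildScenario(scenarioSpec(genomes = c("g1", "g2", "g3"),
                             nCoreFamilies = 5, coreIdentity = 0.9,
                             nSingletons = 2, seed = seed))
}

test_that("a single genome yields only singleton clusters", {
  sc <- buildScenario(scenarioSpec(genomes = "solo", nCoreFamilies = 2,
                                   nSingletons = 3, seed = 31))
  cl <- clusterOrthologs(sc$genomes)
  expect_equal(nrow(cl), 5L)
  expect_equal(length(unique(cl$cluster_id)), 5L)
})

test_that("planted core and singleton counts are recovered exactly", {
  sc <- scenario3(32)
  cl <- clusterOrthologs(sc$genomes)
  part <- partitionPanGenome(cl, names(sc$genomes))
  expect_equal(part$n_core, 5L)
  expect_equal(length(part$singleton_ids), 6L)
  expect_equal(unname(part$venn[c("g1", "g2", "g3")]), rep(2L, 3))
  # clusters agree with the generator's family assignment
  truth <- sc$truth$memberships
  fam_of <- setNames(truth$family, paste(truth$genome_id, truth$protein_id))
  got <- unname(split(paste(cl$genome_id, cl$protein_id), cl$cluster_id))
  want <- unname(split(paste(truth$genome_id, truth$protein_id), fam_of[
    paste(truth$genome_id, truth$protein_id)]))
  expect_setequal(lapply(got, sort), lapply(want, sort))
})

test_that("the clustering is an exhaustive partition, invariant to input
           order, and its Venn cells sum to the cluster count", {
  sc <- scenario3(33)
  cl <- clusterOrthologs(sc$genomes)
  all_prots <- unlist(lapply(sc$genomes, function(g)
    paste(genomeId(g), names(proteome(g)))))
  expect_setequal(paste(cl$genome_id, cl$protein_id), all_prots)
  expect_equal(anyDuplicated(paste(cl$genome_id, cl$protein_id)), 0L)
  part <- partitionPanGenome(cl, names(sc$genomes))
  expect_equal(sum(part$venn), length(unique(cl$cluster_id)))
  # genome input order must not change the cluster composition
  cl_rev <- clusterOrthologs(rev(sc$genomes))
  expect_setequal(
    unname(lapply(split(paste(cl$genome_id, cl$protein_id), cl$cluster_id),
                  sort)),
    unname(lapply(split(paste(cl_rev$genome_id, cl_rev$protein_id),
                        cl_rev$cluster_id), sort)))
})

test_that("unique-core counts match the planted subsets", {
  sc <- buildScenario(scenarioSpec(
    genomes = c("g1", "g2", "g3"), nCoreFamilies = 3,
    uniqueCore = list("g1+g2" = 4), nSingletons = 1, seed = 34))
  part <- partitionPanGenome(clusterOrthologs(sc$genomes),
                             c("g1", "g2", "g3"))
  expect_equal(uniqueCore(part, c("g1", "g2")), 4L)
  expect_equal(uniqueCore(part, c("g2", "g1")), 4L)
  expect_equal(uniqueCore(part, c("g2", "g3")), 0L)
  expect_equal(part$n_core, 3L)
})

test_that("raising the identity cutoff never decreases singleton count", {
  sc <- buildScenario(scenarioSpec(
    genomes = c("g1", "g2"), nCoreFamilies = 4, coreIdentity = 0.75,
    nSingletons = 2, seed = 35))
  n_singletons <- vapply(c(50, 65, 80, 95), function(th) {
    part <- partitionPanGenome(
      clusterOrthologs(sc$genomes, minIdentity = th), c("g1", "g2"))
    length(part$singleton_ids)
  }, 0L)
  expect_true(all(diff(n_singletons) >= 0))
})

test_that("plasmid singleton fractions are computed only for labelled
           replicons and match the planted value", {
  sc <- buildScenario(scenarioSpec(
    genomes = c("g1", "g2"), nCoreFamilies = 2, nSingletons = 10,
    plasmids = list(g1 = list(length = 30000, singletonFraction = 0.4)),
    seed = 36))
  part <- partitionPanGenome(clusterOrthologs(sc$genomes), c("g1", "g2"))
  expect_equal(singletonRepliconFraction(part, sc$genomes$g1), 40)
  # genome without a plasmid: all singletons chromosomal
  expect_equal(singletonRepliconFraction(part, sc$genomes$g2), 0)
  # unlabelled (contig-only) genome: not computable
  p1 <- proteome(sc$genomes$g1)
  len_nt <- 3L * (Biostrings::width(p1) + 1L)
  draft <- GenomeRecord("g1", setNames(randomDNA(1000), "g1_c1"),
                        kind = "contig", proteome = p1,
                        proteinInfo = data.frame(
                          replicon_id = "g1_c1",
                          gene_order_index = seq_along(p1) - 1L,
                          start = cumsum(len_nt) - len_nt + 1L,
                          end = cumsum(len_nt), strand = "+"))
  expect_message(frac <- singletonRepliconFraction(part, draft),
                 "unlabelled")
  expect_true(is.na(frac))
})
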