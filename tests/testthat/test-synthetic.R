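test_that("Markov generation is deterministic under seed and validates its
           transition matrix", {
  tr <- matrix(0.25, 4, 4)
  expect_identical(genMarkovSequence(5000, tr, seed = 81),
                   genMarkovSequence(5000, tr, seed = 81))
  bad <- matrix(0.3, 4, 4)
  expect_error(genMarkovSequence(100, bad), "stochastic")
  expect_error(genGenomeSequence(100, tr), ">= 1000")
})

test_that("uniform i.i.d. chain has analytic rho* of 1 everywhere", {
  pe <- expectedDinucProfile(matrix(0.25, 4, 4))
  expect_equal(unname(rhoValues(pe)), rep(1, 16))
})

test_that("CG-suppressing chain: analytic rho*_CG < 1 and realized profile
           tracks it", {
  tr <- matrix(0.25, 4, 4)
  tr[2, 3] <- 0.10
  tr[2, 1] <- 0.40
  pe <- expectedDinucProfile(tr)
  expect_lt(unname(rhoValues(pe)[["CG"]]), 1)
  g <- genGenomeSequence(1e5, tr, seed = 82)
  pr <- dinucProfile(GenomeRecord("m", c(chr = g$seq)))
  expect_lt(abs(rhoValues(pr)[["CG"]] - rhoValues(pe)[["CG"]]), 0.03)
})

test_that("stationary distribution satisfies pi P = pi", {
  set.seed(83)
  tr <- matrix(runif(16, 0.1, 1), 4, 4)
  tr <- tr / rowSums(tr)
  pi_ <- stationaryDistribution(tr)
  expect_equal(unname(as.vector(pi_ %*% tr)), unname(pi_))
  expect_equal(sum(pi_), 1)
})

test_that("ortholog families hit their identity target", {
  f1 <- genOrthologFamily(300, 2, 1.0, seed = 84)
  expect_identical(f1$proteins[1], f1$proteins[2])
  set.seed(85)
  r <- replicate(30, genOrthologFamily(300, 2, 0.8)$realized_identity[1, 2])
  expect_lt(abs(mean(r) - 0.8), 0.03)
  # a 0.5-identity family falls below the 65% clustering cutoff
  f3 <- genOrthologFamily(300, 2, 0.5, seed = 86)
  expect_lt(f3$realized_identity[1, 2], 0.65)
})

test_that("scenario generation is deterministic and validates its spec", {
  s1 <- buildScenario(scenarioSpec(genomes = c("a", "b"), nCoreFamilies = 2,
                                   nSingletons = 1, seed = 87))
  s2 <- buildScenario(scenarioSpec(genomes = c("a", "b"), nCoreFamilies = 2,
                                   nSingletons = 1, seed = 87))
  expect_identical(as.character(replicons(s1$genomes$a)),
                   as.character(replicons(s2$genomes$a)))
  expect_identical(as.character(proteome(s1$genomes$b)),
                   as.character(proteome(s2$genomes$b)))
  expect_error(scenarioSpec(genomes = "a"), "seed")
  expect_error(scenarioSpec(genomes = "a", uniqueCore = list("a+zz" = 1),
                            seed = 1), "unknown")
  # infeasible layout: genes cannot fit in the replicon
  expect_error(buildScenario(scenarioSpec(
    genomes = "a", genomeLength = 1000, nCoreFamilies = 0,
    nSingletons = 10, seed = 88)), "infeasible")
})

test_that("planted markers round-trip through GenBank emission", {
  sc <- buildScenario(scenarioSpec(
    genomes = "gm", nCoreFamilies = 1, nSingletons = 1,
    markers = list(list(kind = "rieske", genomes = "gm", spacing = 19),
                   list(kind = "luxI", genomes = "gm")),
    seed = 89))
  dir <- withr::local_tempdir()
  writeScenario(sc, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  g2 <- readGenome(file.path(dir, "gm.gbk"), genomeId = "gm")
  truth <- sc$truth$markers
  rk <- Filter(function(m) m$kind == "rieske", truth)[[1]]
  expect_equal(rieskeSpacing(proteome(g2)[[rk$protein_id]]), 19L)
  li <- Filter(function(m) m$kind == "luxI", truth)[[1]]
  expect_equal(checkLuxITriad(
    as.character(proteome(g2)[[li$protein_id]]))$verdict, "pass")
})

test_that("ground truth covers every emitted protein", {
  sc <- buildScenario(defaultScenario(seed = 90))
  emitted <- unlist(lapply(sc$genomes, function(g)
    paste(genomeId(g), names(proteome(g)))))
  listed <- paste(sc$truth$memberships$genome_id,
                  sc$truth$memberships$protein_id)
  expect_setequal(emitted, listed)
})
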