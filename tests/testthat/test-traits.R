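test_that("screening finds exact reference members and respects thresholds", {
  lux <- referenceSet("luxI")
  p <- setNames(lux$proteins[1], "candidate")
  h <- screenProteome(p, lux)
  expect_equal(nrow(h), 1L)
  expect_equal(h$pct_identity, 100)
  # unrelated random proteome: a meaningful negative
  set.seed(51)
  rnd <- Biostrings::AAStringSet(setNames(
    vapply(1:5, function(i) randomProtein(200), ""), paste0("r", 1:5)))
  expect_equal(nrow(screenProteome(rnd, referenceSet("nqr"))), 0L)
})

test_that("a permissive screen is a superset of any stricter screen", {
  set.seed(52)
  prots <- Biostrings::AAStringSet(setNames(
    c(genLuxILike(0.45), genLuxILike(0.7), randomProtein(200)),
    c("far", "near", "noise")))
  loose <- screenProteome(prots, referenceSet("luxI"), minIdentity = 0,
                          maxEvalue = Inf)
  strict <- screenProteome(prots, referenceSet("luxI"))
  expect_true(all(strict$query_id %in% loose$query_id))
  expect_gte(nrow(loose), nrow(strict))
})

test_that("the LuxI triad check reads Arg24/Phe28/Trp34 through gaps and
           substitutions", {
  ref <- referenceSet("luxI")$proteins[[1]]
  expect_equal(checkLuxITriad(as.character(ref))$verdict, "pass")
  intact <- genLuxILike(0.6, seed = 53)
  broken <- genLuxILike(0.6, triadIntact = FALSE, seed = 54)
  expect_equal(checkLuxITriad(intact)$verdict, "pass")
  r <- checkLuxITriad(broken)
  expect_equal(r$verdict, "fail")
  expect_equal(unname(r$residues_found[c("24", "34")]), c("R", "W"))
  expect_equal(unname(r$residues_found[["28"]]), "A")
})

test_that("Rieske spacing matches constructed strings and is local", {
  base17 <- paste0("MA", "CAH", strrep("G", 17), "CAAH", "KL")
  base19 <- paste0("CAH", strrep("G", 19), "CSSH")
  expect_equal(rieskeSpacing(base17), 17L)
  expect_equal(rieskeSpacing(base19), 19L)
  expect_true(is.na(rieskeSpacing("MKLLNNARE")))
  # locality: unrelated flanks do not change the spacing
  set.seed(55)
  flank <- paste(sample(setdiff(.AA, c("C", "H")), 30, TRUE), collapse = "")
  expect_equal(rieskeSpacing(paste0(flank, base17, flank)), 17L)
})

test_that("generated dioxygenase-like proteins carry the requested spacing
           and remain screenable", {
  for (sp in c(17L, 19L)) {
    a <- genArdoLike(sp, seed = 100 + sp)
    expect_equal(rieskeSpacing(a), sp)
    h <- screenProteome(setNames(Biostrings::AAStringSet(a), "q"),
                        referenceSet("ardo"))
    expect_equal(nrow(h), 1L)
  }
})

test_that("cassette detection requires all components within the window on
           one replicon", {
  sc <- buildScenario(scenarioSpec(
    genomes = c("gm", "gn"), nCoreFamilies = 3, nSingletons = 2,
    markers = list(list(kind = "ectABC", genomes = "gm")), seed = 56))
  ect <- list(EctA = referenceSet("ectA"), EctB = referenceSet("ectB"),
              EctC = referenceSet("ectC"))
  call_m <- detectCassette(sc$genomes$gm, ect)
  call_n <- detectCassette(sc$genomes$gn, ect)
  expect_true(call_m$complete)
  expect_lte(call_m$window_span, 20000)
  expect_setequal(call_m$components_found, c("EctA", "EctB", "EctC"))
  expect_false(call_n$complete)
  # partial cassette: EctB alone is incomplete
  pb <- setNames(Biostrings::AAStringSet(
    as.character(referenceSet("ectB")$proteins[[1]])), "b_only")
  gb <- GenomeRecord("gb", setNames(randomDNA(5000), "gb_chr"),
                     kind = "chromosome", proteome = pb)
  call_b <- detectCassette(gb, ect)
  expect_false(call_b$complete)
  expect_equal(call_b$components_found, "EctB")
})

test_that("LuxR solos are called by gene-neighborhood distance", {
  sc <- buildScenario(defaultScenario(seed = 57))
  solos <- luxRSolos(sc$genomes$marineB)
  expect_equal(nrow(solos), 3L)   # two cognate pairs + one solo
  expect_equal(sum(solos$solo), 1L)
  truth <- Filter(function(m) m$kind == "luxRsolo", sc$truth$markers)[[1]]
  expect_equal(solos$protein_id[solos$solo], truth$protein_id)
  expect_true(all(solos$nearest_luxI_distance[!solos$solo] <= 5))
})
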