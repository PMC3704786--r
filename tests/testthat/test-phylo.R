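test_that("Poisson distance matches closed forms under pairwise deletion", {
  expect_equal(poissonDistance("ACDEFG", "ACDEFG"), 0)
  # p = 0.3 -> -ln(0.7)
  a <- strrep("A", 10)
  b <- paste0(strrep("A", 7), strrep("C", 3))
  expect_equal(poissonDistance(a, b), -log(0.7))
  # gap columns excluded from both numerator and denominator
  expect_equal(poissonDistance("AC-DEF", "ACWD-F"), -log(1 - 0))
  expect_equal(poissonDistance("AC-DEF", "ACWDGF" ), -log(1 - 1 / 5) )
  expect_warning(d <- poissonDistance("AAAA", "CCCC"), "infinite")
  expect_true(is.infinite(d))
  expect_error(poissonDistance("----", "AAAA"), "no shared")
})

test_that("distance matrix is symmetric and agrees with the pairwise
           function", {
  set.seed(71)
  aln <- Biostrings::AAStringSet(setNames(
    vapply(1:4, function(i) randomProtein(60), ""), paste0("t", 1:4)))
  m <- poissonDistanceMatrix(aln)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 4))
  expect_equal(m["t1", "t2"],
               poissonDistance(as.character(aln[[1]]),
                               as.character(aln[[2]])))
})

test_that("3-taxon NJ branch lengths solve the three-point formulas", {
  d <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (0.3 + 0.4 - 0.5) / 2, tolerance = 1e-12)
  expect_equal(bl[["b"]], (0.3 + 0.5 - 0.4) / 2, tolerance = 1e-12)
  expect_equal(bl[["c"]], (0.4 + 0.5 - 0.3) / 2, tolerance = 1e-12)
})

test_that("NJ recovers the generating topology of additive matrices and is
           scale-invariant", {
  set.seed(72)
  for (i in 1:20) {
    gen <- additive4()
    tr <- njTree(gen$d)
    expect_equal(njSiblingPair(tr), normalizePair(gen$pair))
    tr2 <- njTree(2 * gen$d)
    expect_equal(njSiblingPair(tr2), normalizePair(gen$pair))
  }
  expect_error(njTree(matrix(c(0, Inf, Inf, 0), 2,
                             dimnames = list(c("a", "b"), c("a", "b")))),
               "3 taxa")
})

test_that("bootstrap supports are high for well-separated clades and seeds
           reproduce", {
  set.seed(73)
  anc <- sample(.AA, 300, TRUE)
  mut <- function(s, n) {
    i <- sample(length(s), n)
    s[i] <- sample(.AA, n, TRUE)
    s
  }
  l <- mut(anc, 50); r <- mut(anc, 50)
  aln <- Biostrings::AAStringSet(vapply(list(
    t1 = mut(l, 10), t2 = mut(l, 10), t3 = mut(r, 10), t4 = mut(r, 10)),
    paste, "", collapse = ""))
  b1 <- bootstrapTree(aln, replicates = 100, seed = 5)
  b2 <- bootstrapTree(aln, replicates = 100, seed = 5)
  expect_equal(ape::write.tree(b1), ape::write.tree(b2))
  sup <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 90))
  # a second seed gives supports within binomial sampling error
  b3 <- bootstrapTree(aln, replicates = 100, seed = 6)
  s3 <- suppressWarnings(as.numeric(b3$node.label))
  expect_true(all(abs(sup - s3) <= 15, na.rm = TRUE))
})

test_that("aligned FASTA round-trips through readAlignment", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 desc", "AC-DE", ">s2", "ACWDE"), f)
  aln <- readAlignment(f)
  expect_equal(names(aln), c("s1", "s2"))
  writeLines(c(">s1", "ACDE", ">s2", "ACD"), f)
  expect_error(readAlignment(f), "length")
})
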