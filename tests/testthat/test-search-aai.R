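test_that("identical proteins give one full-coverage hit at 100% identity", {
  set.seed(21)
  p <- Biostrings::AAStringSet(c(x = randomProtein(200)))
  h <- searchHomologs(p, setNames(p, "y"))
  expect_equal(nrow(h), 1L)
  expect_equal(h$pct_identity, 100)
  expect_equal(h$query_cov, 1)
  expect_equal(h$subject_cov, 1)
})

test_that("search scores equal the brute-force Smith-Waterman oracle", {
  set.seed(22)
  qs <- vapply(1:3, function(i) randomProtein(40), "")
  # subjects: mutated copies plus one unrelated sequence
  mut <- function(s, k) {
    x <- strsplit(s, "")[[1]]
    i <- sample(length(x), k)
    x[i] <- sample(.AA, k, TRUE)
    paste(x, collapse = "")
  }
  ss <- c(mut(qs[1], 8), mut(qs[2], 12), randomProtein(40))
  q <- Biostrings::AAStringSet(setNames(qs, paste0("q", 1:3)))
  s <- Biostrings::AAStringSet(setNames(ss, paste0("s", 1:3)))
  h <- searchHomologs(q, s, minIdentity = 0, minCov = 0, maxEvalue = Inf)
  expect_equal(nrow(h), 9L)
  for (r in seq_len(nrow(h))) {
    expect_equal(h$score[r],
                 swOracle(qs[match(h$query_id[r], names(q))],
                          ss[match(h$subject_id[r], names(s))]))
  }
})

test_that("identity and E-value thresholds drop weak hits", {
  set.seed(23)
  fam <- genOrthologFamily(300, 2, 0.25, seed = 23)  # ~25% identity pair
  a <- Biostrings::AAStringSet(c(p = fam$proteins[1]))
  b <- Biostrings::AAStringSet(c(p = fam$proteins[2]))
  h_all <- searchHomologs(a, b, minIdentity = 0, minCov = 0, maxEvalue = Inf)
  h_flt <- searchHomologs(a, b, minIdentity = 30, minCov = 0,
                          maxEvalue = Inf)
  expect_equal(nrow(h_all), 1L)
  expect_lt(h_all$pct_identity, 30)
  expect_equal(nrow(h_flt), 0L)
})

test_that("reciprocal best hits recover one-to-one families and resolve
           non-reciprocal paralogs", {
  set.seed(24)
  base <- vapply(1:3, function(i) randomProtein(150), "")
  A <- Biostrings::AAStringSet(setNames(base, paste0("a", 1:3)))
  B <- Biostrings::AAStringSet(setNames(base, paste0("b", 1:3)))
  ab <- searchHomologs(A, B, minCov = 0.5)
  ba <- searchHomologs(B, A, minCov = 0.5)
  rbh <- reciprocalBestHits(ab, ba)
  expect_equal(nrow(rbh), 3L)
  expect_equal(sub("a", "", rbh$protein_a), sub("b", "", rbh$protein_b))
  # planted paralog: a1 and a1dup both match b1; only one can be reciprocal
  A2 <- c(A[1], Biostrings::AAStringSet(setNames(
    base[1], "a1dup")))
  ab2 <- searchHomologs(A2, B[1], minCov = 0.5)
  ba2 <- searchHomologs(B[1], A2, minCov = 0.5)
  rbh2 <- reciprocalBestHits(ab2, ba2)
  expect_equal(nrow(rbh2), 1L)
  expect_equal(rbh2$protein_a, "a1")  # deterministic lexicographic tie-break
  # empty input
  expect_equal(nrow(reciprocalBestHits(ab[0, ], ba)), 0L)
})

test_that("AAI is symmetric, order-invariant and exact for self-comparison", {
  set.seed(25)
  pa <- character(8); pb <- character(8)
  for (i in 1:8) {
    f <- genOrthologFamily(150, 2, 0.85)
    pa[i] <- f$proteins[1]
    pb[i] <- f$proteins[2]
  }
  A <- Biostrings::AAStringSet(setNames(pa, paste0("a", 1:8)))
  B <- Biostrings::AAStringSet(setNames(pb, paste0("b", 1:8)))
  r1 <- computeAAI(A, B)
  r2 <- computeAAI(B, A)
  expect_equal(r1$aai, r2$aai)
  expect_equal(r1$n_rbh, 8L)
  perm <- sample(8)
  r3 <- computeAAI(A[perm], B)
  expect_equal(r1$aai, r3$aai)
  self <- computeAAI(A, setNames(A, paste0("x", 1:8)))
  expect_identical(self$aai, 100)
})

test_that("raising the identity threshold never increases RBH count", {
  set.seed(26)
  pa <- character(6); pb <- character(6)
  ident <- c(0.95, 0.9, 0.8, 0.7, 0.55, 0.45)
  for (i in 1:6) {
    f <- genOrthologFamily(180, 2, ident[i])
    pa[i] <- f$proteins[1]
    pb[i] <- f$proteins[2]
  }
  A <- Biostrings::AAStringSet(setNames(pa, paste0("a", 1:6)))
  B <- Biostrings::AAStringSet(setNames(pb, paste0("b", 1:6)))
  n <- vapply(c(30, 50, 70, 90), function(th) {
    ab <- searchHomologs(A, B, minIdentity = th, minCov = 0.7)
    ba <- searchHomologs(B, A, minIdentity = th, minCov = 0.7)
    nrow(reciprocalBestHits(ab, ba))
  }, 0L)
  expect_true(all(diff(n) <= 0))
})
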