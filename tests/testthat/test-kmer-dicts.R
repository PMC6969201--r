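test_that("canonical form matches direct comparison and is idempotent", {
  expect_identical(canonicalKmer("ACG"), "ACG")
  expect_identical(canonicalKmer("TTT"), "AAA")
  set.seed(21)
  for (k in c(3, 7, 15, 31)) {
    x <- vapply(rep(k, 200), randomSeq, character(1))
    expect_identical(canonicalKmer(x), canonicalOracle(x))
    expect_identical(canonicalKmer(canonicalKmer(x)), canonicalKmer(x))
    expect_identical(canonicalKmer(x), canonicalKmer(rcOracle(x)))
  }
  expect_error(canonicalKmer("ACN"), "non-ACGT")
})

test_that("tier sizes derive from genome size and always nest", {
  expect_identical(deriveTierSizes(430e6), c(e = 11L, p = 15L, s = 18L, b = 21L))
  expect_identical(deriveTierSizes(1000), c(e = 4L, p = 7L, s = 10L, b = 13L))
  for (g in c(1e3, 3.7e4, 1e6, 4^12, 1e9, 1e12)) {
    k <- deriveTierSizes(g)
    expect_true(all(diff(k) > 0))
    expect_lte(k["b"], 32L)
    expect_lte(k["p"], 16L)
  }
  expect_error(deriveTierSizes(999), ">= 1000")
})

test_that("insertion counts each N-free k-mer once under canonical orientation", {
  d <- kmerDictSet(tierSizes = c(3, 6, 9, 12))
  insertReads(d, "ACGT")
  # 3-mers of ACGT: ACG (canonical ACG, ctx AC, succ G) and CGT (canonical
  # ACG as well: revcomp(CGT) = ACG), so context AC gains G twice
  expect_equal(querySuccessors(d, "e", "AC"), c(A = 0, C = 0, G = 2, T = 0))
  expect_equal(sum(successorTotals(d)["e"]), 2)

  # N-containing windows are skipped entirely
  d2 <- kmerDictSet(tierSizes = c(3, 6, 9, 12))
  insertReads(d2, "ANGT")
  expect_equal(unname(successorTotals(d2)["e"]), 0)

  # a read and its reverse complement double every touched counter
  set.seed(22)
  r <- randomSeq(40)
  dA <- kmerDictSet(tierSizes = c(4, 6, 9, 12))
  dB <- kmerDictSet(tierSizes = c(4, 6, 9, 12))
  insertReads(dA, r)
  insertReads(dB, c(r, rcOracle(r)))
  for (ctx in unique(substring(r, 1:35, 5:39))) {
    if (grepl("N", ctx)) next
    cc <- canonicalOracle(substr(ctx, 1, 5))
    expect_equal(querySuccessors(dB, "p", substr(ctx, 1, 5)),
                 2 * querySuccessors(dA, "p", substr(ctx, 1, 5)))
  }
})

test_that("worked p-tier query: ATACC statistics reproduce the inserted counts", {
  d <- kmerDictSet(tierSizes = c(4, 6, 9, 12))
  ins <- c(rep("ATACCA", 31), rep("ATACCC", 10), rep("ATACCG", 454),
           rep("ATACCT", 5))
  insertReads(d, ins)
  expect_equal(querySuccessors(d, "p", "ATACC"),
               c(A = 31, C = 10, G = 454, T = 5))
  expect_equal(querySuccessors(d, "p", "GGGGG"), c(A = 0, C = 0, G = 0, T = 0))
})

test_that("partial queries aggregate the 4^missing exact completions", {
  d <- kmerDictSet(tierSizes = c(4, 6, 9, 12))
  set.seed(23)
  reads <- vapply(rep(60, 50), randomSeq, character(1))
  insertReads(d, reads)
  for (i in 1:20) {
    suf <- randomSeq(7)
    expand <- as.vector(outer(c("A", "C", "G", "T"), suf, paste0))
    manual <- Reduce(`+`, lapply(expand, function(cx)
      querySuccessors(d, "s", cx)))
    expect_equal(queryPartial(d, "s", suf, 1), manual)
    suf2 <- randomSeq(6)
    expand2 <- as.vector(outer(
      as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
      suf2, paste0))
    manual2 <- Reduce(`+`, lapply(expand2, function(cx)
      querySuccessors(d, "s", cx)))
    expect_equal(queryPartial(d, "s", suf2, 2), manual2)
  }
  expect_equal(queryPartial(kmerDictSet(tierSizes = c(4, 6, 9, 12)), "s",
                            randomSeq(7), 1),
               c(A = 0, C = 0, G = 0, T = 0))
  expect_error(queryPartial(d, "s", randomSeq(5), 3), "missing")
})

test_that("every query matches a brute-force recount on small inputs", {
  set.seed(24)
  reads <- vapply(rep(80, 40), randomSeq, character(1))
  reads[3] <- paste0(substr(reads[3], 1, 10), "N", substr(reads[3], 12, 80))
  d <- kmerDictSet(tierSizes = c(4, 6, 9, 12))
  insertReads(d, reads)
  for (tier in c("e", "p", "s", "b")) {
    k <- c(e = 4, p = 6, s = 9, b = 12)[[tier]]
    tab <- bruteSuccessorTable(reads, k)
    # totals conserve the number of N-free k-mers inserted
    nIns <- sum(vapply(reads, function(r) {
      n <- nchar(r) - k + 1
      if (n < 1) return(0L)
      sum(!grepl("N", substring(r, 1:n, k:(n + k - 1)), fixed = TRUE))
    }, integer(1)))
    expect_equal(unname(successorTotals(d)[tier]), nIns)
    # every context seen by the oracle agrees, and a sample of random ones
    ctxs <- c(ls(tab), vapply(rep(k - 1, 10), randomSeq, character(1)))
    want <- bruteQueryMatrix(tab, ctxs, k)
    got <- queryMatrix(d, tier, ctxs)
    dimnames(got) <- dimnames(want)
    expect_equal(got, want)
  }
  expect_error(querySuccessors(d, "p", "ACGT"), "context length")
})
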