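test_that("minimizer search matches an exhaustive window scan", {
  set.seed(51)
  for (i in 1:40) {
    L <- sample(3:12, 1)
    n <- sample(L:60, 1)
    s <- randomSeq(n)
    got <- findMinimizer(s, L)
    wins <- substring(s, 1:(n - L + 1), L:n)
    cwins <- canonicalOracle(wins)
    expect_true(got$found)
    expect_identical(got$kmer, min(cwins))
    expect_equal(got$position, which(cwins == min(cwins))[1] - 1)
  }
  # leftmost tie, full-length window, N handling
  expect_equal(findMinimizer("AAAA", 3)$position, 0)
  expect_identical(findMinimizer("ACG", 3)$kmer, "ACG")
  # canonical scan: TTT windows canonicalize to AAA, below ACG
  expect_identical(findMinimizer("TTTACGTTT", 3)$kmer, "AAA")
  expect_identical(findMinimizer("ACGACG", 3)$kmer, "ACG")
  expect_equal(findMinimizer("ACGACG", 3)$position, 0)
  expect_false(findMinimizer("ANANA", 3)$found)
  m <- findMinimizer("NNNACGTNNN", 4)
  expect_true(m$found)
  expect_equal(m$position, 3)
})

test_that("candidate lists count, sort and cap", {
  mb <- minimizerPairDict(bmerLength = 12)
  expect_length(candidateMinimizers(mb, "ACCGAGGTAG"), 0)
  set.seed(52)
  cands <- vapply(rep(12, 12), randomSeq, character(1))
  cands <- unique(canonicalOracle(cands))
  recordPair(mb, "ACCGAGGTAG", cands[1])
  recordPair(mb, "ACCGAGGTAG", cands[1])
  recordPair(mb, "ACCGAGGTAG", cands[2])
  recordPair(mb, "ACCGAGGTAG", cands[1])
  expect_identical(candidateMinimizers(mb, "ACCGAGGTAG"),
                   c(cands[1], cands[2]))
  # equal counts keep insertion order
  recordPair(mb, "ACCGAGGTAG", cands[3])
  expect_identical(candidateMinimizers(mb, "ACCGAGGTAG"),
                   c(cands[1], cands[2], cands[3]))
  # cap at 8 candidates
  for (cand in cands) recordPair(mb, "ACCGAGGTAG", cand)
  expect_lte(length(candidateMinimizers(mb, "ACCGAGGTAG")), 8)
})

test_that("paired archives round-trip and the pair prediction is useful", {
  g <- simulateGenome(60000, seed = 53)
  pe <- simulateReads(g, coverage = 20, readLength = 100, errorRate = 0.001,
                      paired = TRUE, insertMean = 300, insertSd = 30,
                      seed = 54)
  a <- compressFastq(pe$first, pe$second, genomeSize = 60000)
  out <- decompressFastq(a)
  expectRecordsEqual(out$first, pe$first)
  expectRecordsEqual(out$second, pe$second)
  expect_identical(attr(a, "digests"), attr(out, "digests"))

  st <- compressionStats(a)
  n <- st$peHit + st$peMiss
  expect_equal(n, length(pe$first))
  # hit rate after the 10% warm-up exceeds one half
  k <- floor(n * 0.1)
  warm <- compressionStats(compressFastq(pe$first[1:k], pe$second[1:k],
                                         genomeSize = 60000))
  lateRate <- (st$peHit - warm$peHit) / (n - k)
  expect_gt(lateRate, 0.5)

  # reordered paired mode round-trips too
  ar <- compressFastq(pe$first, pe$second, genomeSize = 60000,
                      ordering = "reo")
  or <- decompressFastq(ar)
  sp <- sortReadsForReo(pe)
  expectRecordsEqual(or$first, sp$first)
  expectRecordsEqual(or$second, sp$second)
})

test_that("pairs with short, N-ridden or unpredictable mates still round-trip", {
  set.seed(55)
  first <- FastqRecords(
    c("p1", "p2", "p3"),
    c(randomSeq(100), strrep("N", 40), randomSeq(15)),
    c(strrep("F", 100), strrep("F", 40), strrep("F", 15)))
  second <- FastqRecords(
    c("p1", "p2", "p3"),
    c(randomSeq(100), randomSeq(40), strrep("N", 15)),
    c(strrep("F", 100), strrep("F", 40), strrep("F", 15)))
  a <- compressFastq(first, second, genomeSize = 20000)
  out <- decompressFastq(a)
  expectRecordsEqual(out$first, first)
  expectRecordsEqual(out$second, second)
})
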