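test_that("prefix packing follows the 2-bit big-endian mapping", {
  expect_equal(packPrefix("ATACCG"), 790)
  expect_equal(packPrefix("ATACAT"), 787)
  expect_equal(packPrefix("ATACCG") - packPrefix("ATACAT"), 3)
  expect_equal(packPrefix("AAAAAA"), 0)
  expect_equal(packPrefix("TTTTTT"), 4^6 - 1)
  expect_true(is.na(packPrefix("ATNCCG")))  # N signals the fallback path
  # bijective: distinct prefixes give distinct codes, invertible by base 4
  set.seed(41)
  pre <- unique(vapply(rep(6, 50), randomSeq, character(1)))
  codes <- vapply(pre, packPrefix, numeric(1))
  expect_equal(anyDuplicated(codes), 0)
  digits <- vapply(codes, function(v)
    paste(c("A", "C", "G", "T")[(v %/% 4^(5:0)) %% 4 + 1], collapse = ""),
    character(1))
  expect_identical(unname(digits), pre)
})

test_that("correction triggers only on zero count with a unique max >= 3", {
  expect_identical(maybeCorrect(c(0, 5, 0, 0), "A"), "C")
  expect_identical(maybeCorrect(c(0, 2, 0, 0), "A"), "A")   # max below 3
  expect_identical(maybeCorrect(c(0, 5, 5, 0), "A"), "A")   # ambiguous max
  expect_identical(maybeCorrect(c(1, 5, 0, 0), "A"), "A")   # count not zero
  expect_identical(maybeCorrect(c(0, 5, 0, 0), "N"), "N")   # N never corrected
  expect_identical(maybeCorrect(c(9, 0, 0, 0), "T"), "A")
})

test_that("tier cascade predicts from the longest usable context", {
  d <- kmerDictSet(tierSizes = c(4, 6, 9, 12))
  insertReads(d, c(rep("ATACCA", 31), rep("ATACCC", 10), rep("ATACCG", 454),
                   rep("ATACCT", 5)))
  # 6th symbol: only the p tier is reachable, exact context ATACC
  a <- predictTier(d, "ATACC")
  expect_identical(a$tier, "p")
  expect_equal(a$counts, c(A = 31, C = 10, G = 454, T = 5))
  expect_equal(a$missing, 0)

  # 8th symbol: s tier reachable with one unknown leading symbol (*ATACCGT)
  d2 <- kmerDictSet(tierSizes = c(4, 6, 9, 12))
  insertReads(d2, c(rep("GATACCGTA", 2), rep("GATACCGTC", 155),
                    rep("GATACCGTG", 54), rep("GATACCGTT", 12)))
  a2 <- predictTier(d2, "ATACCGT")
  expect_identical(a2$tier, "s")
  expect_equal(a2$missing, 1)
  expect_equal(a2$counts, c(A = 2, C = 155, G = 54, T = 12))
  expect_equal(a2$counts, queryPartial(d2, "s", "ATACCGT", 1))

  # 14th symbol: the b tier has never seen ACCGTCAGGTA*, fall through to
  # the s tier's GTCAGGTA* statistics
  d3 <- kmerDictSet(tierSizes = c(4, 6, 9, 12))
  insertReads(d3, c(rep("GTCAGGTAA", 15), rep("GTCAGGTAG", 15)))
  a3 <- predictTier(d3, "ATACCGTCAGGTA")
  expect_identical(a3$tier, "s")
  expect_equal(a3$counts, c(A = 15, C = 0, G = 15, T = 0))

  # too little history: order-0
  expect_identical(predictTier(d, "AT")$tier, "order0")
  # N directly before the position blocks every tier
  expect_identical(predictTier(d, "ATACCGNNN")$tier, "order0")
})

test_that("encode/decode round-trips reads and learns across repeats", {
  set.seed(42)
  reads <- FastqRecords(
    id = sprintf("r%d", 1:30),
    sequence = c(vapply(rep(70, 28), randomSeq, character(1)),
                 strrep("N", 50), "ACGTNNNACGT"),
    quality = c(vapply(rep(70, 28), function(n) strrep("E", n), character(1)),
                strrep("E", 50), strrep("E", 11)))
  a <- compressFastq(reads, genomeSize = 20000)
  out <- decompressFastq(a)
  expectRecordsEqual(out, reads)

  # repeating a read makes its second copy cheaper than its first
  r1 <- FastqRecords("x", randomSeq(150), strrep("F", 150))
  one <- compressionStats(compressFastq(r1, genomeSize = 20000))
  two <- compressionStats(compressFastq(r1[c(1, 1)], genomeSize = 20000))
  costFirst <- one$streamBytes[["bases"]]
  costSecond <- two$streamBytes[["bases"]] - costFirst
  expect_lt(costSecond, costFirst / 2)
})

test_that("mean bits/base is non-increasing in coverage", {
  g <- simulateGenome(30000, seed = 43)
  bpb <- vapply(c(1, 4, 20), function(cv) {
    r <- simulateReads(g, coverage = cv, readLength = 100,
                       errorRate = 0.001, seed = 100 + cv)
    compressionStats(compressFastq(r, genomeSize = 30000))$bitsPerBase
  }, numeric(1))
  expect_true(all(diff(bpb) < 0.05 * bpb[-length(bpb)]))  # 5% sampling slack
})

test_that("REO prefixes delta-code against the previous read", {
  g <- simulateGenome(20000, seed = 44)
  r <- simulateReads(g, coverage = 8, readLength = 90, seed = 45)
  s <- sortReadsForReo(r)
  packed <- vapply(substr(sequences(s), 1, 12), packPrefix, numeric(1))
  packed <- packed[!is.na(packed)]
  expect_true(all(diff(packed) >= 0))  # sorted reads: deltas never negative

  a <- compressFastq(r, genomeSize = 20000, ordering = "reo",
                     tierSizes = c(6, 12, 15, 18))
  out <- decompressFastq(a)
  expectRecordsEqual(out, s)
  # equal consecutive prefixes (delta 0) and N prefixes both survive
  odd <- FastqRecords(c("a", "b", "c"),
                      c("NNACGTACGTACGTACGT", "ACGTACGTACGTACGTAC",
                        "ACGTACGTACGTACGTGG"),
                      c(strrep("F", 18), strrep("F", 18), strrep("F", 18)))
  a2 <- compressFastq(odd, genomeSize = 20000, ordering = "reo")
  expectRecordsEqual(decompressFastq(a2), sortReadsForReo(odd))
})

test_that("corrections keep encoder and decoder dictionaries in lockstep", {
  # high-coverage genome with sprinkled errors: corrections certainly fire
  g <- simulateGenome(15000, seed = 46)
  r <- simulateReads(g, coverage = 25, readLength = 100, errorRate = 0.01,
                     seed = 47)
  a <- compressFastq(r, genomeSize = 15000, blockSize = 200000)
  st <- compressionStats(a)
  expect_gt(st$nCorrections, 0)
  out <- decompressFastq(a)
  expectRecordsEqual(out, r)  # lossless despite in-stream correction
  expect_identical(attr(a, "digests"), attr(out, "digests"))
  expect_gt(length(attr(a, "digests")), 1)  # several blocks compared
})
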