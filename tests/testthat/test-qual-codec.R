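test_that("binning tables map scores to their representatives", {
  expect_equal(binQuality(35, "8"), 37)
  expect_equal(binQuality(c(0, 1, 2, 9, 10, 19, 20, 24, 25, 29, 30, 34, 35,
                            39, 40, 93), "8"),
               c(0, 0, 6, 6, 15, 15, 22, 22, 27, 27, 33, 33, 37, 37, 40, 40))
  expect_equal(binQuality(c(0, 9, 10, 19, 20, 29, 30, 93), "4"),
               c(6, 6, 15, 15, 25, 25, 37, 37))
  expect_equal(binQuality(0:93, "96"), 0:93)  # identity
  expect_equal(sort(unique(binQuality(0:93, "2"))), c(6, 37))  # 2 preimages
  # idempotence: every representative maps to itself
  for (m in c("8", "4", "2"))
    expect_equal(binQuality(binQuality(0:93, m), m), binQuality(0:93, m))
  expect_error(binQuality(95, "8"), "out of range")
})

test_that("quality contexts are injective while the packed space fits", {
  h1 <- c(0, 1)
  h2 <- c(1, 0)
  expect_false(qualityContextId(5, h1, "96") == qualityContextId(5, h2, "96"))
  expect_false(qualityContextId(5, h1, "96") == qualityContextId(6, h1, "96"))
  # read start: empty history equals the all-zero history
  expect_equal(qualityContextId(0, integer(), "2"),
               qualityContextId(0, rep(0, 10), "2"))
  # position bucket saturates
  expect_equal(qualityContextId(400, h1, "96"), qualityContextId(63, h1, "96"))
  set.seed(71)
  ids <- replicate(100, qualityContextId(sample(0:15, 1),
                                         sample(0:7, 6, TRUE), "8"))
  expect_lte(max(ids), 2^22)
})

test_that("quality streams code losslessly at full resolution, lossily binned below", {
  g <- simulateGenome(10000, seed = 72)
  r <- simulateReads(g, coverage = 6, readLength = 80, seed = 73)
  out96 <- decompressFastq(compressFastq(r, genomeSize = 10000, quality = "96"))
  expect_identical(qualities(out96), qualities(r))

  for (m in c("8", "4", "2")) {
    a <- compressFastq(r, genomeSize = 10000, quality = m)
    out <- decompressFastq(a)
    expect_identical(qualities(out), expectedQualities(qualities(r), m))
    # idempotently lossy: re-compressing the binned output is lossless
    a2 <- compressFastq(out, genomeSize = 10000, quality = m)
    expect_identical(qualities(decompressFastq(a2)), qualities(out))
  }

  outN <- decompressFastq(compressFastq(r, genomeSize = 10000,
                                        quality = "none"))
  expect_identical(qualities(outN),
                   vapply(nchar(qualities(r)), function(n) strrep("I", n),
                          character(1)))
})

test_that("reduced-resolution input passes through a lossy mode unchanged", {
  # a file that already uses 4 distinct scores is lossless under Q4 and Q8
  set.seed(74)
  n <- 60
  qs <- vapply(1:n, function(i)
    intToUtf8(33 + sample(c(5, 18, 28, 39), 45, TRUE)), character(1))
  r <- FastqRecords(sprintf("r%d", 1:n),
                    vapply(rep(45, n), randomSeq, character(1)), qs)
  for (m in c("8", "4")) {
    out <- decompressFastq(compressFastq(r, genomeSize = 20000, quality = m))
    expect_identical(qualities(out), qs)
  }
  # under Q2 it must still bin (4 values cannot fit 2)
  out2 <- decompressFastq(compressFastq(r, genomeSize = 20000, quality = "2"))
  expect_identical(qualities(out2), expectedQualities(qs, "2"))
})

test_that("constant-quality reads cost almost nothing after warm-up", {
  n <- 400
  r <- FastqRecords(sprintf("r%d", 1:n),
                    vapply(rep(100, n), function(k) {
                      paste(sample(c("A", "C", "G", "T"), k, TRUE),
                            collapse = "")
                    }, character(1)),
                    rep(strrep("F", 100), n))
  st <- compressionStats(compressFastq(r, genomeSize = 20000))
  expect_lt(st$streamBytes[["qualities"]] / (n * 100), 0.01)  # < 0.08 bits/score
})
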