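test_that("sorting for the reordered mode is stable and by full sequence", {
  r <- FastqRecords(c("t", "a", "c"), c("TTT", "AAA", "CCC"),
                    c("111", "222", "333"))
  s <- sortReadsForReo(r)
  expect_identical(sequences(s), c("AAA", "CCC", "TTT"))
  expect_identical(readIDs(s), c("a", "c", "t"))  # ids travel with reads

  dup <- FastqRecords(c("x1", "x2", "x3"), c("AC", "AC", "AA"),
                      c("11", "22", "33"))
  sd <- sortReadsForReo(dup)
  expect_identical(readIDs(sd), c("x3", "x1", "x2"))  # duplicates keep order
})

test_that("original-order lossless archives restore the file byte-exactly", {
  g <- simulateGenome(25000, seed = 81)
  r <- simulateReads(g, coverage = 6, readLength = c(60, 110), seed = 82)
  f <- tempfile(fileext = ".fastq")
  writeFastq(r, f)
  arc <- tempfile(fileext = ".fqpk")
  compressFastq(f, output = arc, genomeSize = 25000)
  out <- tempfile(fileext = ".fastq")
  decompressFastq(arc, output = out)
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(f, "raw", file.size(f)))
})

test_that("reordered archives preserve the content multiset", {
  g <- simulateGenome(25000, seed = 83)
  r <- simulateReads(g, coverage = 5, readLength = 90, seed = 84)
  out <- decompressFastq(compressFastq(r, genomeSize = 25000,
                                       ordering = "reo"))
  expect_identical(recordTuples(out), recordTuples(r))
  expect_identical(sequences(out), sort(sequences(r), method = "radix"))
})

test_that("identical input and settings give byte-identical archives", {
  g <- simulateGenome(12000, seed = 85)
  r <- simulateReads(g, coverage = 4, seed = 86)
  a1 <- compressFastq(r, genomeSize = 12000, ordering = "reo", quality = "8")
  a2 <- compressFastq(r, genomeSize = 12000, ordering = "reo", quality = "8")
  expect_identical(as.raw(a1), as.raw(a2))
})

test_that("empty inputs yield a valid empty archive", {
  a <- compressFastq(FastqRecords(), genomeSize = 50000)
  out <- decompressFastq(a)
  expect_equal(length(out), 0L)
  info <- archiveInfo(as.raw(a))
  expect_equal(info@nUnits, 0)
  expect_equal(info@nBlocks, 0)
})

test_that("corruption and truncation are detected, not decoded", {
  g <- simulateGenome(10000, seed = 87)
  r <- simulateReads(g, coverage = 4, seed = 88)
  a <- as.raw(compressFastq(r, genomeSize = 10000))
  expect_error(decompressFastq(a[1:(length(a) - 30)]), "truncated")
  bad <- a
  bad[length(bad) - 200] <- as.raw(bitwXor(as.integer(bad[length(bad) - 200]),
                                           170L))
  expect_error(decompressFastq(bad), "checksum mismatch in block")
  nonsense <- as.raw(sample(0:255, 100, TRUE))
  expect_error(decompressFastq(nonsense), "magic|truncated|corrupt")
})

test_that("the header describes the archive and blocks are honored", {
  g <- simulateGenome(20000, seed = 89)
  r <- simulateReads(g, coverage = 6, readLength = 70, seed = 90)
  a <- compressFastq(r, genomeSize = 20000, quality = "4", ids = "instrument",
                     blockSize = 50000, tierSizes = c(5, 9, 13, 16))
  info <- archiveInfo(as.raw(a))
  expect_false(info@paired)
  expect_false(info@reordered)
  expect_identical(info@quality, "4")
  expect_identical(info@ids, "instrument")
  expect_equal(info@genomeSize, 20000)
  expect_identical(unname(info@tierSizes), c(5L, 9L, 13L, 16L))
  expect_equal(info@nUnits, length(r))
  expect_gt(info@nBlocks, 1)
  expect_equal(sum(info@blockUnits), length(r))
  # show() prints the key fields
  txt <- paste(capture.output(show(info)), collapse = "\n")
  expect_match(txt, "single-end")
  expect_match(txt, "e=5 p=9 s=13 b=16")

  # dictionaries persist across blocks; digests align block by block
  out <- decompressFastq(a)
  expect_identical(attr(a, "digests"), attr(out, "digests"))
  expect_equal(length(attr(a, "digests")), unname(info@nBlocks))
})

test_that("base streams beat naive 2-bit packing at 10x coverage", {
  g <- simulateGenome(40000, seed = 91)
  r <- simulateReads(g, coverage = 10, readLength = 100, errorRate = 0.001,
                     seed = 92)
  st <- compressionStats(compressFastq(r, genomeSize = 40000))
  expect_lt(st$bitsPerBase, 2)
})
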