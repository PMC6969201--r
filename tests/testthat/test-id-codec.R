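test_that("tokenization splits on non-alphanumerics and types digit runs", {
  tk <- tokenizeId("SRR327342.7 7 length=100")
  expect_identical(tk$tokens, c("SRR327342", "7", "7", "length", "100"))
  expect_identical(tk$numeric, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_identical(tk$separators, c("", ".", " ", " ", "=", ""))

  tk0 <- tokenizeId("")
  expect_length(tk0$tokens, 0)
  expect_identical(tk0$separators, "")

  # leading zeros stay literal so the width survives
  expect_identical(tokenizeId("007")$numeric, FALSE)
  expect_identical(tokenizeId("0")$numeric, TRUE)

  # reassembly is exact for arbitrary printable ids
  set.seed(61)
  pool <- c(LETTERS, letters, 0:9, ".", ":", " ", "/", "#", "=", "-", "_")
  for (i in 1:50) {
    id <- paste(sample(pool, sample(0:30, 1), replace = TRUE), collapse = "")
    expect_identical(detokenizeId(tokenizeId(id)), id)
  }
})

test_that("id streams round-trip losslessly for every structure pattern", {
  seqs <- function(n) vapply(rep(30, n), randomSeq, character(1))
  set.seed(62)
  ids <- c(
    "SRR1.1 1 length=30",    # template
    "SRR1.2 2 length=30",    # numeric deltas
    "SRR1.2 2 length=30",    # all-equal tokens
    "SRR1.10 10 length=30",  # larger jump
    "q:weird header",        # structure change -> literal
    "q:weird header",
    "",                      # empty id
    "#### 0007 ####",        # literal digits
    "SRR1.11 11 length=30",  # back to the template shape
    strrep("z9", 40))        # long mixed token
  r <- FastqRecords(ids, seqs(length(ids)), vapply(rep(30, length(ids)),
                    function(n) strrep("F", n), character(1)))
  out <- decompressFastq(compressFastq(r, genomeSize = 20000))
  expect_identical(readIDs(out), ids)

  # random id soup round-trips too
  pool <- c(LETTERS, 0:9, ".", " ", ":", "=", "/")
  ids2 <- vapply(1:200, function(i)
    paste(sample(pool, sample(0:25, 1), replace = TRUE), collapse = ""),
    character(1))
  r2 <- FastqRecords(ids2, seqs(200), vapply(rep(30, 200), function(n)
    strrep("F", n), character(1)))
  expect_identical(readIDs(decompressFastq(compressFastq(r2, genomeSize = 20000))),
                   ids2)
})

test_that("ids differing only in serial coordinates cost under 4 bytes each", {
  set.seed(63)
  n <- 2000
  ids <- sprintf("SRR1265495.%d %d length=40", 1:n, 1:n)
  r <- FastqRecords(ids, vapply(rep(40, n), randomSeq, character(1)),
                    vapply(rep(40, n), function(k) strrep("F", k), character(1)))
  st <- compressionStats(compressFastq(r, genomeSize = 20000))
  expect_lt(st$streamBytes[["ids"]] / n, 4)

  # tile/x/y-style ids with drifting coordinates stay compact too
  x <- cumsum(sample(0:40, n, TRUE))
  y <- sample(1000:1999, n, TRUE)
  ids2 <- sprintf("M00123:45:ABCDE:1:2106:%d:%d", x, y)
  r2 <- FastqRecords(ids2, sequences(r), qualities(r))
  st2 <- compressionStats(compressFastq(r2, genomeSize = 20000))
  expect_lt(st2$streamBytes[["ids"]] / n, 4)
})

test_that("instrument mode keeps the move-to-front name list; discard mode renumbers", {
  mkrec <- function(ids) FastqRecords(ids, vapply(rep(20, length(ids)),
                         randomSeq, character(1)),
                         rep(strrep("F", 20), length(ids)))
  ids <- c("A.1 x", "B.7 y", "A.9 z", "B.2", "B.3", "C1:only")
  out <- decompressFastq(compressFastq(mkrec(ids), genomeSize = 20000,
                                       ids = "instrument"))
  expect_identical(readIDs(out), c("A", "B", "A", "B", "B", "C1"))

  out2 <- decompressFastq(compressFastq(mkrec(ids), genomeSize = 20000,
                                        ids = "none"))
  expect_identical(readIDs(out2), paste0("r", 1:6))
})
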