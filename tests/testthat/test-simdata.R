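test_that("generation is deterministic under a seed", {
  g1 <- simulateGenome(5000, seed = 7)
  g2 <- simulateGenome(5000, seed = 7)
  expect_identical(g1, g2)
  expect_false(identical(g1, simulateGenome(5000, seed = 8)))
  r1 <- simulateReads(g1, coverage = 3, seed = 9)
  r2 <- simulateReads(g1, coverage = 3, seed = 9)
  expect_identical(sequences(r1), sequences(r2))
  expect_identical(qualities(r1), qualities(r2))
  expect_error(simulateGenome(0), ">= 1")
})

test_that("base composition is uniform within binomial bounds", {
  g <- simulateGenome(1e5, seed = 10)
  cnt <- table(strsplit(g, "")[[1]])
  expect_setequal(names(cnt), c("A", "C", "G", "T"))
  # 3 sigma for Binomial(1e5, 1/4)
  expect_true(all(abs(cnt - 25000) < 3 * sqrt(1e5 * 0.25 * 0.75)))
})

test_that("read count, error rate and error-free extraction behave as specified", {
  g <- simulateGenome(1e5, seed = 11)
  r <- simulateReads(g, coverage = 10, readLength = 100, seed = 12)
  expect_equal(length(r), 10000L)

  # with no errors every read is an exact substring of the genome (or its
  # reverse complement); checked against Biostrings matching
  r0 <- simulateReads(g, coverage = 0.05, readLength = 80, errorRate = 0,
                      seed = 13)
  gs <- Biostrings::DNAString(g)
  for (s in sequences(r0)) {
    hitF <- Biostrings::countPattern(s, gs) > 0
    hitR <- Biostrings::countPattern(rcOracle(s), gs) > 0
    expect_true(hitF || hitR)
  }

  # observed mismatch fraction tracks the requested substitution rate
  rate <- 0.01
  re <- simulateReads(g, coverage = 2, readLength = 100, errorRate = rate,
                      seed = 14)
  nb <- sum(nchar(sequences(re)))
  # align by construction: regenerate without errors under the same seed
  r0b <- simulateReads(g, coverage = 2, readLength = 100, errorRate = 0,
                       seed = 14)
  mm <- sum(mapply(function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  }, sequences(re), sequences(r0b)))
  expect_lt(abs(mm / nb - rate), 3 * sqrt(rate * (1 - rate) / nb) + 2e-4)
})

test_that("paired reads have sane inserts, ids and quality profile", {
  g <- simulateGenome(5e4, seed = 15)
  pe <- simulateReads(g, coverage = 4, readLength = 100, errorRate = 0,
                      paired = TRUE, insertMean = 300, insertSd = 30,
                      seed = 16)
  expect_equal(length(pe$first), length(pe$second))
  expect_equal(length(pe$first), round(4 * 5e4 / 100 / 2))
  expect_match(readIDs(pe$first)[1], "^sim\\.1 1 length=100$")

  # mates face each other: mate2 reverse-complemented relative to mate1's
  # strand, so the pair re-aligns to the genome around one fragment
  gs <- Biostrings::DNAString(g)
  ok <- 0
  for (i in 1:20) {
    s1 <- sequences(pe$first)[i]
    s2 <- sequences(pe$second)[i]
    p1 <- c(Biostrings::start(Biostrings::matchPattern(s1, gs)),
            Biostrings::start(Biostrings::matchPattern(rcOracle(s1), gs)))
    p2 <- c(Biostrings::start(Biostrings::matchPattern(s2, gs)),
            Biostrings::start(Biostrings::matchPattern(rcOracle(s2), gs)))
    gap <- abs(outer(p1, p2, "-"))
    if (any(gap <= 300 + 5 * 30)) ok <- ok + 1
  }
  expect_gte(ok, 19)  # allow one repeat-placement ambiguity

  # qualities decay along the read on average
  q <- do.call(rbind, lapply(qualities(pe$first)[1:200], function(s)
    utf8ToInt(s) - 33))
  expect_gt(mean(q[, 1:10]), mean(q[, 91:100]))
  expect_true(all(q >= 2 + 33 - 33 & q <= 40))
})
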