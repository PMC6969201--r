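# shared test utilities: independent oracles and fixture builders

# reverse complement / canonical form via Biostrings (independent oracle)
rcOracle <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
canonicalOracle <- function(x) {
  rc <- rcOracle(x)
  ifelse(x <= rc, x, rc)
}

# brute-force successor recount over a set of reads: returns an environment
# mapping every canonical (k-1)-mer context to its A/C/G/T successor counts
bruteSuccessorTable <- function(reads, k) {
  kmers <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) character() else substring(r, 1:(n - k + 1), k:n)
  }))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  tab <- new.env(parent = emptyenv())
  if (length(kmers) == 0) return(tab)
  ck <- canonicalOracle(kmers)
  tb <- table(context = substr(ck, 1, k - 1), successor = substr(ck, k, k))
  for (ctx in rownames(tb)) {
    cur <- c(A = 0, C = 0, G = 0, T = 0)
    cur[colnames(tb)] <- tb[ctx, ]
    tab[[ctx]] <- cur
  }
  tab
}

# oracle for successor queries: the count of context+x aggregates both
# orientations, i.e. it is the canonical k-mer's count.  Vectorized over
# contexts; returns a contexts x ACGT matrix.
bruteQueryMatrix <- function(tab, ctxs, k) {
  bases <- c("A", "C", "G", "T")
  allk <- as.vector(outer(ctxs, bases, paste0))
  ck <- canonicalOracle(allk)
  cctx <- substr(ck, 1, k - 1)
  csuc <- substr(ck, k, k)
  cnt <- vapply(seq_along(allk), function(i) {
    v <- tab[[cctx[i]]]
    if (is.null(v)) 0 else v[[csuc[i]]]
  }, numeric(1))
  matrix(cnt, nrow = length(ctxs), dimnames = list(ctxs, bases))
}

bruteQueryOracle <- function(tab, ctx, k) bruteQueryMatrix(tab, ctx, k)[1, ]

# implementation-side counterpart for batch comparison
queryMatrix <- function(d, tier, ctxs) {
  t(vapply(ctxs, function(ctx) querySuccessors(d, tier, ctx), numeric(4)))
}

# random ACGT string from an explicit seed-free draw (caller controls RNG)
randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

randomRecords <- function(n, len = 50) {
  FastqRecords(
    id = sprintf("read.%d %d", seq_len(n), seq_len(n)),
    sequence = vapply(rep(len, n), randomSeq, character(1)),
    quality = vapply(seq_len(n), function(i)
      intToUtf8(sample(33:73, len, replace = TRUE)), character(1)))
}

# content tuples for multiset comparisons
recordTuples <- function(x) {
  sort(paste(readIDs(x), sequences(x), qualities(x), sep = "\r"))
}

# expected instrument name: first alphanumeric run of the ID
instrumentOracle <- function(id) {
  sub("^[^A-Za-z0-9]*([A-Za-z0-9]*).*$", "\\1", id)
}

# expected decoder output for a lossy quality mode, using the table the
# compressor stores in the header (identity when the input already has at
# most as many distinct scores as the mode allows)
expectedQualities <- function(qual, quality) {
  if (quality == "96") return(qual)
  if (quality == "none")
    return(vapply(nchar(qual), function(n) strrep("I", n), character(1)))
  observed <- fqpack:::cppDistinctQuals(qual)
  tab <- fqpack:::.qualBinTable(quality, observed)
  old <- intToUtf8(33:126)
  new <- intToUtf8(33 + tab$rep[tab$sym + 1L])
  chartr(old, new, qual)
}

# full expected decompressor output for any mode combination
expectedOutput <- function(r1, r2 = NULL, ordering = "oo", quality = "96",
                           ids = "lossless") {
  paired <- !is.null(r2)
  if (ordering == "reo") {
    if (paired) {
      pr <- sortReadsForReo(list(first = r1, second = r2))
      r1 <- pr$first; r2 <- pr$second
    } else r1 <- sortReadsForReo(r1)
  }
  allq <- c(qualities(r1), if (paired) qualities(r2))
  fixIds <- function(x, n0) {
    switch(ids,
           lossless = readIDs(x),
           instrument = instrumentOracle(readIDs(x)),
           none = paste0("r", seq_len(length(x))))
  }
  fixQual <- function(x) {
    if (quality %in% c("96", "none")) expectedQualities(qualities(x), quality)
    else {
      observed <- fqpack:::cppDistinctQuals(allq)
      tab <- fqpack:::.qualBinTable(quality, observed)
      chartr(intToUtf8(33:126), intToUtf8(33 + tab$rep[tab$sym + 1L]),
             qualities(x))
    }
  }
  e1 <- FastqRecords(fixIds(r1), sequences(r1), fixQual(r1), validate = FALSE)
  if (!paired) return(e1)
  list(first = e1,
       second = FastqRecords(fixIds(r2), sequences(r2), fixQual(r2),
                             validate = FALSE))
}

expectRecordsEqual <- function(got, want) {
  expect_identical(readIDs(got), readIDs(want))
  expect_identical(sequences(got), sequences(want))
  expect_identical(qualities(got), qualities(want))
}
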