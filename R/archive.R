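.idModes <- c("lossless", "instrument", "none")

.asRecords <- function(input, what = "input") {
  if (is(input, "FastqRecords")) return(input)
  if (is.character(input) && length(input) == 1) return(readFastq(input))
  stop(what, " must be a FastqRecords object or a file path")
}

#' Sort reads by sequence for the reordered mode
#'
#' Stable lexicographic sort by the full base sequence (first mate's
#' sequence for pairs); IDs and qualities travel with their read.  Sorted
#' packed p-mer prefixes are non-decreasing, which is what makes the
#' prefix-delta stream cheap.
#'
#' @param x a [FastqRecords-class] object, or a pair list as returned by
#'   [pairReads()].
#' @return the permuted object of the same shape.
#' @export
sortReadsForReo <- function(x) {
  if (is(x, "FastqRecords")) {
    o <- order(x@sequence, method = "radix")
    return(x[o])
  }
  if (is.list(x) && all(c("first", "second") %in% names(x))) {
    o <- order(x$first@sequence, method = "radix")
    return(list(first = x$first[o], second = x$second[o]))
  }
  stop("x must be a FastqRecords object or a pairReads() list")
}

#' Compress FASTQ reads into an FQPK archive
#'
#' Single-end or paired-end reads are coded block by block: bases through
#' the tiered k-mer prediction cascade with rank-transform coding and
#' in-stream error correction, IDs by tokenized differential coding,
#' qualities under position/history contexts, and (for pairs) second reads
#' via minimizer-pair prediction.  In the reordered mode reads are first
#' sorted by sequence and read prefixes are delta-coded.  Dictionaries and
#' models persist across blocks; the decompressor replays the identical
#' prediction and update sequence.
#'
#' @param input FASTQ path or [FastqRecords-class] (single-end, or mate 1).
#' @param input2 optional second FASTQ path or [FastqRecords-class] (mate 2);
#'   supplying it selects paired-end mode.
#' @param output optional path for the archive; when NULL the archive is
#'   only returned as a raw vector.
#' @param genomeSize declared approximate genome size in bases; sets the
#'   k-mer tier sizes via [deriveTierSizes()].
#' @param ordering \code{"oo"} keeps the original read order (lossless
#'   order); \code{"reo"} sorts reads by sequence first, which compresses
#'   markedly better but makes order part of the loss.
#' @param quality quality resolution: \code{"96"} (lossless), \code{"8"},
#'   \code{"4"}, \code{"2"} or \code{"none"}.
#' @param ids ID handling: \code{"lossless"}, \code{"instrument"} (keep the
#'   instrument name only) or \code{"none"} (decoder regenerates
#'   \code{r1}, \code{r2}, ...).
#' @param blockSize block capacity in raw FASTQ bytes (default 16 MiB).
#' @param tierSizes optional explicit \code{c(e, p, s, b)} override.
#' @return raw archive bytes, invisibly when written to a file.  Attributes:
#'   \code{stats} (stream byte counts, input bases, bits/base of the base
#'   streams, pair-prediction hit counts, corrections) and \code{digests}
#'   (per-block state digests; [decompressFastq()] reproduces them exactly).
#' @examples
#' reads <- simulateReads(simulateGenome(5000, seed = 1), coverage = 4,
#'                        readLength = 80, seed = 2)
#' a <- compressFastq(reads, genomeSize = 5000)
#' out <- decompressFastq(a)
#' identical(sequences(out), sequences(reads))
#' @export
compressFastq <- function(input, input2 = NULL, output = NULL, genomeSize,
                          ordering = c("oo", "reo"),
                          quality = c("96", "8", "4", "2", "none"),
                          ids = c("lossless", "instrument", "none"),
                          blockSize = 16 * 1024^2, tierSizes = NULL) {
  ordering <- match.arg(ordering)
  quality <- match.arg(as.character(quality), .qualModes)
  ids <- match.arg(ids)
  if (!is.numeric(genomeSize) || genomeSize < 1000)
    stop("genomeSize must be a number >= 1000")
  if (blockSize < 1) stop("blockSize must be positive")
  if (is.null(tierSizes)) tierSizes <- deriveTierSizes(genomeSize)
  tierSizes <- as.integer(tierSizes)
  if (length(tierSizes) != 4 || any(diff(tierSizes) <= 0) ||
      tierSizes[1] < 2 || tierSizes[4] > 32 || tierSizes[2] > 16)
    stop("tierSizes must satisfy 1 < e < p < s < b <= 32 and p <= 16")

  r1 <- .asRecords(input)
  paired <- !is.null(input2)
  r2 <- if (paired) .asRecords(input2, "input2") else FastqRecords(validate = FALSE)
  if (paired && length(r1) != length(r2))
    stop("paired inputs differ in record count")

  if (ordering == "reo") {
    if (paired) {
      pr <- sortReadsForReo(list(first = r1, second = r2))
      r1 <- pr$first; r2 <- pr$second
    } else {
      r1 <- sortReadsForReo(r1)
    }
  }

  qmode <- .qualModeCode(quality)
  if (qmode != 4L) {
    observed <- if (quality == "96") NULL else
      cppDistinctQuals(c(r1@quality, if (paired) r2@quality))
    tab <- .qualBinTable(quality, observed)
  } else {
    tab <- list(sym = integer(), rep = integer())
  }

  res <- cppCompress(r1@id, r1@sequence, r1@quality, r2@id, r2@sequence,
                     r2@quality, paired, ordering == "reo", qmode,
                     match(ids, .idModes) - 1L, genomeSize, blockSize,
                     tierSizes, tab$sym, tab$rep)

  archive <- res$archive
  baseBytes <- unname(res$streamBytes["bases"] + res$streamBytes["prefix"])
  attr(archive, "stats") <- list(
    streamBytes = res$streamBytes,
    archiveBytes = length(archive),
    nBases = res$nBases,
    nBlocks = res$nBlocks,
    bitsPerBase = if (res$nBases > 0) 8 * baseBytes / res$nBases else NA_real_,
    peHit = res$peHit, peMiss = res$peMiss,
    nCorrections = res$nCorrections)
  attr(archive, "digests") <- res$digests
  if (!is.null(output)) {
    writeBin(as.raw(archive), output)
    return(invisible(archive))
  }
  archive
}

#' Decompress an FQPK archive
#'
#' Rebuilds the reads by replaying the encoder's prediction, model-update
#' and correction sequence; per-block checksums guard against corruption.
#' Original-order archives restore the input order; reordered archives
#' emit the sequence-sorted order (the content multiset is preserved).
#'
#' @param archive raw archive bytes or a file path.
#' @param output,output2 optional FASTQ output paths (mate 1 / mate 2;
#'   \code{output2} only for paired archives).
#' @return a [FastqRecords-class] object, or for paired archives a list
#'   with elements \code{first} and \code{second}.  Attribute
#'   \code{digests} holds the per-block state digests for symmetry checks
#'   against the encoder.
#' @export
decompressFastq <- function(archive, output = NULL, output2 = NULL) {
  if (is.character(archive))
    archive <- readBin(archive, "raw", file.size(archive))
  stopifnot(is.raw(archive))
  res <- cppDecompress(archive)
  r1 <- FastqRecords(res$id1, res$seq1, res$qual1, validate = FALSE)
  if (res$paired) {
    r2 <- FastqRecords(res$id2, res$seq2, res$qual2, validate = FALSE)
    out <- list(first = r1, second = r2)
    if (!is.null(output)) writeFastq(r1, output)
    if (!is.null(output2)) writeFastq(r2, output2)
  } else {
    if (!is.null(output2)) stop("output2 given for a single-end archive")
    out <- r1
    if (!is.null(output)) writeFastq(r1, output)
  }
  attr(out, "digests") <- res$digests
  out
}

#' Inspect an FQPK archive header
#'
#' @param archive raw archive bytes or a file path.
#' @return an [FqArchiveInfo-class] object.
#' @export
archiveInfo <- function(archive) {
  if (is.character(archive))
    archive <- readBin(archive, "raw", file.size(archive))
  stopifnot(is.raw(archive))
  h <- cppArchiveInfo(archive)
  new("FqArchiveInfo",
      paired = h$paired, reordered = h$reo,
      quality = .qualModes[h$qualMode + 1L],
      ids = .idModes[h$idMode + 1L],
      genomeSize = h$genomeSize, blockSize = h$blockSize,
      tierSizes = h$tierSizes, nUnits = h$nUnits, nBlocks = h$nBlocks,
      blockUnits = as.numeric(h$blockUnits),
      blockStreamBytes = h$blockStreamBytes)
}

#' Compression statistics of an archive produced in this session
#'
#' @param archive value returned by [compressFastq()].
#' @return the \code{stats} attribute (stream bytes, bits/base, pair hits,
#'   corrections), or NULL when absent.
#' @export
compressionStats <- function(archive) attr(archive, "stats")
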