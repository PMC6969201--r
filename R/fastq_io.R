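#' Read a 4-line FASTQ file
#'
#' Parses the plain 4-line FASTQ dialect (no wrapped sequences).  Plain and
#' gzip-compressed files are both accepted.  Two documented normalizations
#' are applied and are not reversed on writing: bases are uppercased, and any
#' ID repeated on the \code{+} line is discarded (regenerated as a bare
#' \code{+}).  After uppercasing, any base outside \{A,C,G,T,N\} is an error.
#'
#' @param path file path (optionally \code{.gz}) or a connection.
#' @return a [FastqRecords-class] object.
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "FFFF"), f)
#' readFastq(f)
#' @export
readFastq <- function(path) {
  lines <- readLines(path)
  parseFastqLines(lines)
}

#' Parse FASTQ text lines into records
#'
#' @param lines character vector of raw FASTQ lines (4 per record).
#' @return a [FastqRecords-class] object.
#' @export
parseFastqLines <- function(lines) {
  n <- length(lines)
  if (n == 0L)
    return(FastqRecords(validate = FALSE))
  if (n %% 4L != 0L)
    stop("malformed FASTQ: record ", n %/% 4L + 1L,
         " is truncated (file has ", n, " lines)")
  ids <- lines[seq.int(1L, n, 4L)]
  seqs <- toupper(lines[seq.int(2L, n, 4L)])
  plus <- lines[seq.int(3L, n, 4L)]
  quals <- lines[seq.int(4L, n, 4L)]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad))
    stop("malformed FASTQ: record ", bad[1],
         " does not start with '@' (got ", substr(ids[bad[1]], 1, 20), ")")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ: record ", bad[1], " has no '+' separator line")
  v <- cppValidateRecords(seqs, quals)
  if (!v$ok)
    stop("malformed FASTQ: record ", v$index, ": ", v$reason)
  FastqRecords(substring(ids, 2L), seqs, quals, validate = FALSE)
}

#' Write records as 4-line FASTQ
#'
#' Inverse of [readFastq()]: writing then re-reading reproduces the records
#' byte-identically (the \code{+} line is always bare).
#'
#' @param x a [FastqRecords-class] object.
#' @param path output file path; a \code{.gz} suffix triggers gzip output.
#' @return the path, invisibly.
#' @export
writeFastq <- function(x, path) {
  stopifnot(is(x, "FastqRecords"))
  lines <- as.character(rbind(paste0("@", x@id), x@sequence, "+", x@quality))
  if (endsWith(path, ".gz")) {
    con <- gzfile(path, "wb")
    on.exit(close(con))
    writeLines(lines, con)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' Pair two read sets positionally
#'
#' @param first,second [FastqRecords-class] objects of equal length (mate 1
#'   and mate 2 files of a paired-end run).
#' @return a list with elements \code{first} and \code{second}.
#' @export
pairReads <- function(first, second) {
  stopifnot(is(first, "FastqRecords"), is(second, "FastqRecords"))
  if (length(first) != length(second))
    stop("paired inputs differ in record count (", length(first), " vs ",
         length(second), ")")
  list(first = first, second = second)
}

#' Split records into blocks by raw FASTQ byte size
#'
#' Greedy partition: records are appended to the current block while its raw
#' 4-line FASTQ footprint stays within \code{blockSizeBytes}; a single record
#' larger than the limit forms its own block.  Concatenating the blocks
#' restores the input order.
#'
#' @param x a [FastqRecords-class] object.
#' @param blockSizeBytes positive block capacity in bytes (default 16 MiB,
#'   the block size used by the archive pipeline).
#' @return a list of [FastqRecords-class] objects.
#' @export
splitBlocks <- function(x, blockSizeBytes = 16 * 1024^2) {
  stopifnot(is(x, "FastqRecords"), blockSizeBytes > 0)
  n <- length(x)
  if (n == 0L) return(list())
  sz <- nchar(x@id) + nchar(x@sequence) + nchar(x@quality) + 6
  blocks <- list()
  start <- 1L
  cur <- 0
  for (i in seq_len(n)) {
    if (cur > 0 && cur + sz[i] > blockSizeBytes) {
      blocks[[length(blocks) + 1L]] <- x[start:(i - 1L)]
      start <- i
      cur <- 0
    }
    cur <- cur + sz[i]
  }
  blocks[[length(blocks) + 1L]] <- x[start:n]
  blocks
}
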