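#' FastqRecords: a set of FASTQ records
#'
#' Parallel character vectors holding the ID line (without the leading
#' \code{@}), the base sequence over the alphabet \{A,C,G,T,N\}, and the
#' quality string (ASCII 33..126, one character per base).
#'
#' @slot id character vector of read identifiers.
#' @slot sequence character vector of base strings.
#' @slot quality character vector of quality strings.
#'
#' @examples
#' fq <- FastqRecords("r1", "ACGT", "FFFF")
#' length(fq)
#' sequences(fq)
#' @export
setClass("FastqRecords",
         representation(id = "character", sequence = "character",
                        quality = "character"))

setValidity("FastqRecords", function(object) {
  n <- length(object@id)
  if (length(object@sequence) != n || length(object@quality) != n)
    return("id, sequence and quality must have the same length")
  v <- cppValidateRecords(object@sequence, object@quality)
  if (!v$ok)
    return(sprintf("record %d: %s", v$index, v$reason))
  TRUE
})

#' Construct a FastqRecords object
#'
#' @param id,sequence,quality parallel character vectors (see class docs).
#' @param validate check invariants (equal lengths, ACGTN alphabet, quality
#'   range). Constructors on already-validated data may skip this.
#' @return a [FastqRecords-class] object.
#' @export
FastqRecords <- function(id = character(), sequence = character(),
                         quality = character(), validate = TRUE) {
  x <- new("FastqRecords", id = as.character(id),
           sequence = as.character(sequence), quality = as.character(quality))
  if (validate) validObject(x)
  x
}

#' @describeIn FastqRecords-class number of records
#' @param x a FastqRecords object.
#' @export
setMethod("length", "FastqRecords", function(x) length(x@id))

#' @describeIn FastqRecords-class subset records
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "FastqRecords", function(x, i, j, ..., drop = TRUE) {
  FastqRecords(x@id[i], x@sequence[i], x@quality[i], validate = FALSE)
})

setMethod("show", "FastqRecords", function(object) {
  n <- length(object)
  cat(sprintf("FastqRecords with %d record%s\n", n, if (n == 1) "" else "s"))
  if (n > 0) {
    k <- min(n, 3L)
    for (i in seq_len(k)) {
      s <- object@sequence[i]
      if (nchar(s) > 40) s <- paste0(substr(s, 1, 40), "...")
      cat(sprintf("  @%s  %s\n", object@id[i], s))
    }
    if (n > k) cat(sprintf("  ... and %d more\n", n - k))
  }
  invisible(object)
})

#' @rdname FastqRecords-class
#' @param x a FastqRecords object.
#' @export
readIDs <- function(x) x@id

#' @rdname FastqRecords-class
#' @export
sequences <- function(x) x@sequence

#' @rdname FastqRecords-class
#' @export
qualities <- function(x) x@quality

# ---------------------------------------------------------------------------

#' Tiered canonical k-mer successor dictionaries
#'
#' Holds the four successor-count dictionaries over canonical e-, p-, s- and
#' b-mers (e < p < s < b) that drive base prediction.  Contexts of k-1 bases
#' map to counts of their four observed successors; a k-mer and its reverse
#' complement reinforce the same entry.
#'
#' @slot ptr external pointer to the native dictionary set.
#' @seealso [kmerDictSet()], [insertReads()], [querySuccessors()]
#' @export
setClass("KmerDictSet", representation(ptr = "externalptr"))

#' @describeIn KmerDictSet-class create an empty dictionary set. Either give
#'   \code{genomeSize} (tier sizes derived via [deriveTierSizes()]) or the
#'   four explicit sizes.
#' @param genomeSize approximate genome length in bases.
#' @param tierSizes integer vector \code{c(e, p, s, b)} overriding the derived
#'   sizes.
#' @export
kmerDictSet <- function(genomeSize = NULL, tierSizes = NULL) {
  if (is.null(tierSizes)) {
    if (is.null(genomeSize))
      stop("give either genomeSize or tierSizes")
    tierSizes <- deriveTierSizes(genomeSize)
  }
  tierSizes <- as.integer(tierSizes)
  if (length(tierSizes) != 4 || any(diff(tierSizes) <= 0) ||
      tierSizes[4] > 32 || tierSizes[1] < 2)
    stop("tier sizes must satisfy 1 < e < p < s < b <= 32")
  new("KmerDictSet", ptr = cppDictsNew(tierSizes[1], tierSizes[2],
                                       tierSizes[3], tierSizes[4]))
}

setMethod("show", "KmerDictSet", function(object) {
  k <- cppDictsTierSizes(object@ptr)
  tot <- cppDictsTotals(object@ptr)
  cat("KmerDictSet (canonical k-mer successor counts)\n")
  cat(sprintf("  tiers: e=%d p=%d s=%d b=%d\n", k[1], k[2], k[3], k[4]))
  cat(sprintf("  k-mers counted: e=%.0f p=%.0f s=%.0f b=%.0f\n",
              tot[1], tot[2], tot[3], tot[4]))
  invisible(object)
})

# ---------------------------------------------------------------------------

#' Adaptive rank model
#'
#' The "Model" dictionary: maps a context descriptor (answering tier,
#' position bucket, quantized ordered counts, corrected-previous flag) to
#' adaptive frequencies of the symbol ranks 0..4.  Frequencies start at
#' (16, 8, 4, 2, 1), grow by 32 per observation and are halved (floor 1)
#' when their sum exceeds 2^16 -- a dynamic-Markov-coder-like rule that
#' adapts far faster than classical PPM statistics.
#'
#' @slot ptr external pointer to the native model table.
#' @seealso [rankModel()], [rankFreqs()], [rankUpdate()]
#' @export
setClass("RankModel", representation(ptr = "externalptr"))

#' @describeIn RankModel-class create a fresh model (all contexts at the
#'   initial frequencies).
#' @export
rankModel <- function() new("RankModel", ptr = cppRankModelNew())

setMethod("show", "RankModel", function(object) {
  cat("RankModel: adaptive rank-frequency table",
      "(init 16,8,4,2,1; +32/obs; halved above 2^16)\n")
  invisible(object)
})

# ---------------------------------------------------------------------------

#' Minimizer-pair dictionary for paired-end prediction
#'
#' Maps the minimizer of a first read to a counted, descending-sorted list of
#' b-mers observed in the corresponding second reads (at most 8 candidates
#' per key; ties keep insertion order).
#'
#' @slot ptr external pointer to the native dictionary.
#' @slot bmerLength length of the stored candidate b-mers.
#' @seealso [minimizerPairDict()], [recordPair()], [candidateMinimizers()]
#' @export
setClass("MinimizerPairDict",
         representation(ptr = "externalptr", bmerLength = "integer"))

#' @describeIn MinimizerPairDict-class create an empty dictionary.
#' @param bmerLength length of the candidate b-mers to be stored (<= 32).
#' @export
minimizerPairDict <- function(bmerLength) {
  bmerLength <- as.integer(bmerLength)
  if (bmerLength < 1 || bmerLength > 32)
    stop("bmerLength must be in 1..32")
  new("MinimizerPairDict", ptr = cppMbNew(), bmerLength = bmerLength)
}

setMethod("show", "MinimizerPairDict", function(object) {
  cat(sprintf("MinimizerPairDict (candidate b-mers of length %d, cap 8)\n",
              object@bmerLength))
  invisible(object)
})

# ---------------------------------------------------------------------------

#' Archive header information
#'
#' Parsed header of an FQPK archive: mode flags, k-mer tier sizes, quality
#' binning table and per-block stream sizes.  Archives are self-describing;
#' decompression needs nothing beyond the archive itself.
#'
#' @slot paired,reordered logical mode flags.
#' @slot quality,ids character mode names.
#' @slot genomeSize,blockSize,nUnits,nBlocks numeric scalars.
#' @slot tierSizes named integer vector (e, p, s, b).
#' @slot blockUnits numeric vector: records (or pairs) per block.
#' @slot blockStreamBytes matrix of per-block stream byte counts.
#' @seealso [archiveInfo()]
#' @export
setClass("FqArchiveInfo",
         representation(paired = "logical", reordered = "logical",
                        quality = "character", ids = "character",
                        genomeSize = "numeric", blockSize = "numeric",
                        tierSizes = "integer", nUnits = "numeric",
                        nBlocks = "numeric", blockUnits = "numeric",
                        blockStreamBytes = "matrix"))

setMethod("show", "FqArchiveInfo", function(object) {
  cat("FQPK archive\n")
  cat(sprintf("  layout: %s, %s order\n",
              if (object@paired) "paired-end" else "single-end",
              if (object@reordered) "reordered (sequence-sorted)" else "original"))
  cat(sprintf("  quality mode: %s   id mode: %s\n", object@quality, object@ids))
  cat(sprintf("  declared genome size: %.0f bases\n", object@genomeSize))
  cat(sprintf("  k-mer tiers: e=%d p=%d s=%d b=%d\n", object@tierSizes[1],
              object@tierSizes[2], object@tierSizes[3], object@tierSizes[4]))
  cat(sprintf("  %.0f %s in %.0f block(s) of <= %.0f bytes\n", object@nUnits,
              if (object@paired) "pairs" else "reads", object@nBlocks,
              object@blockSize))
  sb <- colSums(object@blockStreamBytes)
  cat("  stream bytes:", paste(sprintf("%s=%.0f", names(sb), sb),
                               collapse = " "), "\n")
  invisible(object)
})
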