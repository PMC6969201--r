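#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement, making dictionary statistics
#' strand-independent.  Idempotent; N is not allowed (callers exclude
#' N-containing windows).
#'
#' @param kmer character vector of ACGT strings.
#' @return character vector of canonical k-mers.
#' @examples
#' canonicalKmer(c("ACG", "TTT"))  # "ACG", "AAA"
#' @export
canonicalKmer <- function(kmer) cppCanonical(as.character(kmer))

#' Derive k-mer tier sizes from a declared genome size
#'
#' The four tier lengths grow with the genome so that b-mer contexts remain
#' mostly unique in the genome:
#' \code{b = clamp(ceil(log4(G)) + 6, 13, 32)}, \code{s = b - 3},
#' \code{p = min(16, s - 3)}, \code{e = max(4, p - 4)}.  The result always
#' satisfies \code{e < p < s < b}; p <= 16 so a p-mer prefix packs into 2p
#' bits for the reordered-mode delta coding.
#'
#' @param genomeSize declared genome length in bases (>= 1000).  An accurate
#'   value is not required; a rough order of magnitude suffices.
#' @return named integer vector \code{c(e, p, s, b)}.
#' @examples
#' deriveTierSizes(430e6)  # e=11 p=15 s=18 b=21
#' @export
deriveTierSizes <- function(genomeSize) {
  if (!is.numeric(genomeSize) || length(genomeSize) != 1 || genomeSize < 1000)
    stop("genomeSize must be a single number >= 1000")
  b <- as.integer(ceiling(log2(genomeSize) / 2 - 1e-9)) + 6L
  b <- max(13L, min(32L, b))
  s <- b - 3L
  p <- min(16L, s - 3L)
  e <- max(4L, p - 4L)
  c(e = e, p = p, s = s, b = b)
}

#' Insert reads into the k-mer dictionaries
#'
#' Every N-free k-mer of each read is counted once per tier under its
#' canonical orientation: the last base is the successor, the preceding
#' k-1 bases the context.  Counts saturate at 2^16 - 1.
#'
#' @param dicts a [KmerDictSet-class] object (updated in place).
#' @param sequences character vector of ACGTN read sequences.
#' @return the dictionary set, invisibly.
#' @export
insertReads <- function(dicts, sequences) {
  stopifnot(is(dicts, "KmerDictSet"))
  cppDictsInsert(dicts@ptr, as.character(sequences))
  invisible(dicts)
}

.tierIndex <- function(tier) {
  i <- match(match.arg(as.character(tier), c("e", "p", "s", "b")),
             c("e", "p", "s", "b"))
  i - 1L
}

#' Query successor counts of a context
#'
#' @param dicts a [KmerDictSet-class] object.
#' @param tier one of \code{"e"}, \code{"p"}, \code{"s"}, \code{"b"}.
#' @param context N-free ACGT string of length k-1 for the chosen tier.
#' @return named numeric vector of A/C/G/T successor counts (all zero when
#'   the context was never seen).
#' @export
querySuccessors <- function(dicts, tier, context) {
  stopifnot(is(dicts, "KmerDictSet"))
  cppDictsQuery(dicts@ptr, .tierIndex(tier), context)
}

#' Query successor counts with unknown leading symbols
#'
#' Element-wise sum of [querySuccessors()] over all completions of 1 or 2
#' unknown leading context symbols (the \code{*ATACCGT*}-style queries used
#' early in a read, before k-1 symbols of history exist).  Deeper gaps must
#' fall back to a smaller tier.
#'
#' @inheritParams querySuccessors
#' @param knownSuffix the known trailing part of the context.
#' @param missing number of unknown leading symbols (1 or 2);
#'   \code{nchar(knownSuffix) + missing} must equal k-1.
#' @return named numeric vector of aggregated A/C/G/T successor counts.
#' @export
queryPartial <- function(dicts, tier, knownSuffix, missing) {
  stopifnot(is(dicts, "KmerDictSet"))
  cppDictsQueryPartial(dicts@ptr, .tierIndex(tier), knownSuffix,
                       as.integer(missing))
}

#' Tier sizes of a dictionary set
#' @param dicts a [KmerDictSet-class] object.
#' @return named integer vector \code{c(e, p, s, b)}.
#' @export
tierSizes <- function(dicts) {
  stopifnot(is(dicts, "KmerDictSet"))
  cppDictsTierSizes(dicts@ptr)
}

#' Total successor counts per tier
#'
#' Pre-saturation, the total equals the number of N-free k-mers inserted
#' into the tier (conservation invariant).
#'
#' @param dicts a [KmerDictSet-class] object.
#' @return named numeric vector of per-tier totals.
#' @export
successorTotals <- function(dicts) {
  stopifnot(is(dicts, "KmerDictSet"))
  cppDictsTotals(dicts@ptr)
}
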