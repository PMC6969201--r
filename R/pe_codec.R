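#' Find the minimizer of a read
#'
#' The minimizer is the lexicographically smallest canonical L-mer over all
#' N-free windows of the read (leftmost window on ties).  Reads from nearby
#' genome positions usually share a minimizer, which is what makes the
#' minimizer-pair dictionary predictive for paired ends.
#'
#' @param sequence ACGTN string.
#' @param L minimizer length (<= 32).
#' @return list with \code{found} (logical), \code{kmer} (the canonical
#'   minimizer) and \code{position} (0-based leftmost window offset; -1 when
#'   not found).
#' @export
findMinimizer <- function(sequence, L) {
  stopifnot(is.character(sequence), length(sequence) == 1, L >= 1, L <= 32)
  cppFindMinimizer(sequence, as.integer(L))
}

#' Record a minimizer pair
#'
#' Registers that second-read b-mer \code{m2} co-occurred with first-read
#' minimizer \code{m1}.  Candidate lists stay sorted by descending count
#' (ties keep insertion order) and are capped at 8 entries; when full, the
#' lowest-count entry is evicted for a new candidate.
#'
#' @param x a [MinimizerPairDict-class] object (updated in place).
#' @param m1 first-read minimizer (ACGT string).
#' @param m2 second-read b-mer (ACGT string of length \code{bmerLength}).
#' @return the dictionary, invisibly.
#' @export
recordPair <- function(x, m1, m2) {
  stopifnot(is(x, "MinimizerPairDict"))
  if (nchar(m2) != x@bmerLength)
    stop("m2 must have length ", x@bmerLength)
  cppMbRecord(x@ptr, m1, m2)
  invisible(x)
}

#' Ordered candidate b-mers for a first-read minimizer
#'
#' @param x a [MinimizerPairDict-class] object.
#' @param m1 first-read minimizer (ACGT string).
#' @return character vector of candidate b-mers, most frequent first (empty
#'   when \code{m1} was never recorded).
#' @export
candidateMinimizers <- function(x, m1) {
  stopifnot(is(x, "MinimizerPairDict"))
  cppMbCandidates(x@ptr, m1, x@bmerLength)
}
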