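#' Pack a read prefix into a 2p-bit integer
#'
#' Big-endian 2-bit packing with A=00, C=01, G=10, T=11; bijective on ACGT
#' strings of fixed length.  In the reordered mode consecutive sorted reads
#' share long prefixes, so differences of packed prefixes are small numbers
#' that delta-code cheaply.
#'
#' @param prefix ACGT string of length at most 16.
#' @return the packed value as a numeric scalar, or \code{NA} when the
#'   prefix contains N (signalling the literal fallback path, not an error).
#' @examples
#' packPrefix("ATACCG")  # 790
#' packPrefix("ATACAT")  # 787
#' @export
packPrefix <- function(prefix) {
  stopifnot(is.character(prefix), length(prefix) == 1)
  v <- cppPackPrefix(prefix)
  if (v < 0) NA_real_ else v
}

#' In-stream sequencing-error correction rule
#'
#' Consulted when the largest (b) tier supplied the prediction: if the
#' current symbol was never seen after this context (count 0) while some
#' other base has a unique count of at least 3, the read is assumed to carry
#' a sequencing error at this position.  The original symbol is still
#' encoded; only the working copy used for subsequent contexts and
#' dictionary insertion is replaced, which keeps erroneous k-mers out of the
#' dictionaries.  N is never corrected.
#'
#' @param counts numeric vector of 4 successor counts (A,C,G,T) from the
#'   b-tier prediction.
#' @param symbol the current base, one of "A","C","G","T","N".
#' @return the (possibly corrected) base character.
#' @examples
#' maybeCorrect(c(0, 5, 0, 0), "A")  # "C"
#' maybeCorrect(c(0, 2, 0, 0), "A")  # "A": max below 3
#' @export
maybeCorrect <- function(counts, symbol) {
  stopifnot(length(counts) == 4)
  code <- match(symbol, c("A", "C", "G", "T", "N")) - 1L
  if (is.na(code)) stop("symbol must be one of A, C, G, T, N")
  c("A", "C", "G", "T", "N")[cppMaybeCorrect(as.integer(counts), code) + 1L]
}

#' Tier-cascade prediction for the next base
#'
#' Tries the dictionaries largest-first (b, s, p, e).  A tier is usable when
#' at least e-1 history symbols exist and the needed context -- allowing at
#' most 2 unknown leading symbols, answered via [queryPartial()] -- contains
#' no N.  The first tier with a non-zero count vector answers; if all usable
#' tiers are zero the smallest usable tier's (zero) answer is returned, and
#' with no usable tier the order-0 fallback is used.
#'
#' @param dicts a [KmerDictSet-class] object.
#' @param history the already-processed prefix of the read (ACGTN string);
#'   the prediction is for the symbol at position \code{nchar(history)}.
#' @return list with \code{tier} ("order0","e","p","s","b"), \code{counts}
#'   (named A/C/G/T vector) and \code{missing} (unknown leading symbols of a
#'   partial query, 0..2).
#' @export
predictTier <- function(dicts, history) {
  stopifnot(is(dicts, "KmerDictSet"), is.character(history),
            length(history) == 1)
  cppPredict(dicts@ptr, history)
}
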