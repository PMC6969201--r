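#' Rank transform of successor counts
#'
#' Reorders the alphabet by descending successor count (stable: ties broken
#' lexicographically), with N always at rank 4.  Coding ranks instead of
#' symbols concentrates probability mass on rank 0 regardless of which base
#' dominates a context.
#'
#' @param counts numeric vector of 4 successor counts, in A, C, G, T order.
#' @return character vector of length 5: the symbols at ranks 0..4.
#' @examples
#' rankSymbols(c(31, 10, 454, 5))  # G A C T N
#' @export
rankSymbols <- function(counts) {
  stopifnot(length(counts) == 4, all(counts >= 0))
  c("A", "C", "G", "T", "N")[cppRankOrder(as.integer(counts)) + 1L]
}

.rankTier <- function(tier) {
  match(match.arg(as.character(tier), c("order0", "e", "p", "s", "b")),
        c("order0", "e", "p", "s", "b")) - 1L
}

#' Current rank frequencies for a model context
#'
#' The context descriptor is formed from the answering tier, the read
#' position (bucketed), the quantized top-two ordered counts and the
#' corrected-previous-base flag.  A never-seen context returns the initial
#' vector (16, 8, 4, 2, 1).
#'
#' @param model a [RankModel-class] object.
#' @param tier which dictionary answered: \code{"order0"}, \code{"e"},
#'   \code{"p"}, \code{"s"} or \code{"b"}.
#' @param position 0-based position of the symbol in its read.
#' @param counts the 4 successor counts the prediction returned (A,C,G,T).
#' @param correctedPrev was the preceding base replaced by the correction
#'   rule?
#' @return numeric vector of 5 adaptive frequencies for ranks 0..4.
#' @export
rankFreqs <- function(model, tier, position, counts, correctedPrev = FALSE) {
  stopifnot(is(model, "RankModel"))
  cppRankModelFreqs(model@ptr, .rankTier(tier), as.integer(position),
                    as.integer(counts), isTRUE(correctedPrev))
}

#' Record an observed rank in the model
#'
#' Adds the increment (32) to the observed rank's frequency and halves all
#' five frequencies (floor 1) when their sum exceeds 2^16.
#'
#' @inheritParams rankFreqs
#' @param rank the observed symbol rank, 0..4.
#' @return the model, invisibly.
#' @export
rankUpdate <- function(model, tier, position, counts, correctedPrev = FALSE,
                       rank) {
  stopifnot(is(model, "RankModel"))
  cppRankModelUpdate(model@ptr, .rankTier(tier), as.integer(position),
                     as.integer(counts), isTRUE(correctedPrev),
                     as.integer(rank))
  invisible(model)
}
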