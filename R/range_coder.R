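#' Byte-oriented range coder
#'
#' The entropy-coding back end shared by every codec in the package: a
#' carry-propagating range coder with a 32-bit range and byte
#' renormalization whenever the range drops below 2^24.  Symbols are coded
#' under explicit cumulative-frequency intervals \code{[cumLo, cumHi)} out
#' of \code{total}; totals must stay at or below 2^24 so renormalization is
#' exact.  A decoder fed the identical sequence of tables reproduces the
#' symbols exactly, at a cost within a fraction of a percent of the Shannon
#' bound.
#'
#' @slot ptr external pointer to the native coder state.
#' @seealso [rangeEncoder()], [encodeSymbol()], [flushEncoder()],
#'   [rangeDecoder()], [decodeTarget()], [decodeUpdate()]
#' @aliases RangeDecoder-class
#' @export
setClass("RangeEncoder", representation(ptr = "externalptr"))

#' @rdname RangeEncoder-class
#' @export
setClass("RangeDecoder", representation(ptr = "externalptr"))

#' @describeIn RangeEncoder-class create a fresh encoder.
#' @export
rangeEncoder <- function() new("RangeEncoder", ptr = cppRcEncNew())

#' Encode one symbol interval
#'
#' @param enc a [RangeEncoder-class] object.
#' @param cumLo,cumHi cumulative frequency bounds of the symbol,
#'   \code{0 <= cumLo < cumHi <= total}.
#' @param total table total, at most 2^24.
#' @return the encoder, invisibly.
#' @export
encodeSymbol <- function(enc, cumLo, cumHi, total) {
  stopifnot(is(enc, "RangeEncoder"))
  cppRcEncSymbol(enc@ptr, cumLo, cumHi, total)
  invisible(enc)
}

#' Finish encoding and collect the output bytes
#'
#' Emits the tail bytes that make every coded symbol decodable.  Flushing
#' twice is an error.
#'
#' @param enc a [RangeEncoder-class] object.
#' @return raw vector of coded bytes.
#' @export
flushEncoder <- function(enc) {
  stopifnot(is(enc, "RangeEncoder"))
  cppRcEncFlush(enc@ptr)
}

#' @describeIn RangeEncoder-class create a decoder over coded bytes.
#' @param bytes raw vector produced by [flushEncoder()].
#' @export
rangeDecoder <- function(bytes) {
  stopifnot(is.raw(bytes))
  new("RangeDecoder", ptr = cppRcDecNew(bytes))
}

#' Scaled cumulative target for the next symbol
#'
#' Returns a value \code{v} with \code{cumLo <= v < cumHi} for the symbol
#' the encoder coded at this step; the caller locates the symbol in its
#' table and then calls [decodeUpdate()] with that symbol's interval.
#'
#' @param dec a [RangeDecoder-class] object.
#' @param total the table total the encoder used at this step.
#' @return numeric scalar in \code{[0, total)}.
#' @export
decodeTarget <- function(dec, total) {
  stopifnot(is(dec, "RangeDecoder"))
  cppRcDecTarget(dec@ptr, total)
}

#' Consume the decoded symbol's interval
#'
#' @inheritParams decodeTarget
#' @param cumLo,cumHi the decoded symbol's cumulative interval.
#' @return the decoder, invisibly.
#' @export
decodeUpdate <- function(dec, cumLo, cumHi, total) {
  stopifnot(is(dec, "RangeDecoder"))
  cppRcDecUpdate(dec@ptr, cumLo, cumHi, total)
  invisible(dec)
}
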