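#' Tokenize a read identifier
#'
#' Splits an ID into maximal alphanumeric tokens with the separator
#' characters preserved between them (\code{separators} always has one more
#' element than \code{tokens}: leading, inter-token and trailing runs).  A
#' pure-digit token is numeric unless it has a leading zero (delta coding
#' would lose the width) or exceeds 18 digits; mixed tokens are literals.
#' Reassembly via [detokenizeId()] reproduces the ID exactly.
#'
#' @param id a single ID string (printable ASCII).
#' @return list with \code{tokens} (character), \code{numeric} (logical) and
#'   \code{separators} (character).
#' @examples
#' tokenizeId("SRR327342.7 7 length=100")
#' @export
tokenizeId <- function(id) {
  stopifnot(is.character(id), length(id) == 1)
  cppTokenizeId(id)
}

#' Reassemble a tokenized identifier
#'
#' @param x a token list as returned by [tokenizeId()].
#' @return the original ID string.
#' @export
detokenizeId <- function(x) {
  n <- length(x$tokens)
  out <- x$separators[1]
  if (n > 0)
    for (i in seq_len(n))
      out <- paste0(out, x$tokens[i], x$separators[i + 1])
  out
}
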