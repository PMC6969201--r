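.qualModes <- c("96", "8", "4", "2", "none")

.qualModeCode <- function(quality) {
  match(match.arg(as.character(quality), .qualModes), .qualModes) - 1L
}

# default binning tables (0-based quality scores 0..93 -> representative).
# Q8 follows the de-facto Illumina 8-level bins; Q4/Q2 coarsen them.
.qualBinTable <- function(mode, observed = NULL) {
  q <- 0:93
  if (mode == "96") {
    return(list(sym = as.integer(q), rep = as.integer(q)))
  }
  alpha <- c("8" = 8L, "4" = 4L, "2" = 2L)[[mode]]
  if (!is.null(observed) && length(observed) > 0 &&
      length(observed) <= alpha) {
    # input already at (or below) this resolution: identity on the observed
    # values, so the mode is lossless for such files
    rep <- sort(as.integer(observed))
    sym <- vapply(q, function(v) which.min(abs(rep - v)) - 1L, integer(1))
    return(list(sym = sym, rep = rep))
  }
  if (mode == "8") {
    rep <- c(0L, 6L, 15L, 22L, 27L, 33L, 37L, 40L)
    cuts <- c(2, 10, 20, 25, 30, 35, 40)
  } else if (mode == "4") {
    rep <- c(6L, 15L, 25L, 37L)
    cuts <- c(10, 20, 30)
  } else {
    rep <- c(6L, 37L)
    cuts <- 20
  }
  sym <- as.integer(findInterval(q, cuts))
  list(sym = sym, rep = rep)
}

#' Bin quality scores to a reduced resolution
#'
#' Five resolutions are supported: 96 (identity), 8 (Illumina-style 8-level
#' bins), 4, 2, and none.  The fixed tables are
#' \itemize{
#'   \item Q8: 0-1 -> 0, 2-9 -> 6, 10-19 -> 15, 20-24 -> 22, 25-29 -> 27,
#'     30-34 -> 33, 35-39 -> 37, >= 40 -> 40
#'   \item Q4: 0-9 -> 6, 10-19 -> 15, 20-29 -> 25, >= 30 -> 37
#'   \item Q2: < 20 -> 6, >= 20 -> 37
#' }
#' Binning is idempotent: every representative maps to itself.  During
#' compression an identity table is used instead whenever the input already
#' holds at most as many distinct values as the mode allows, so such files
#' round-trip losslessly; the table in force is stored in the archive
#' header.
#'
#' @param q integer quality scores (0..93, i.e. ASCII minus 33).
#' @param quality mode, one of \code{"96"}, \code{"8"}, \code{"4"},
#'   \code{"2"}.
#' @return integer vector of binned scores.
#' @examples
#' binQuality(35, "8")  # 37
#' @export
binQuality <- function(q, quality = "8") {
  quality <- match.arg(as.character(quality), .qualModes)
  if (quality == "none")
    stop("quality mode 'none' discards scores; nothing to bin")
  tab <- .qualBinTable(quality)
  cppApplyQualTable(as.integer(q), tab$sym, tab$rep)
}

#' Quality-model context identifier
#'
#' The coding context of a quality symbol combines its read position
#' (bucketed at 64 positions for the 96-value mode, 16 otherwise) with the
#' previous h binned scores (h = 2, 6, 9, 10 for modes 96, 8, 4, 2), packed
#' radix-alphabet.  All four context spaces fit within 2^22 contexts, so the
#' mapping is injective.
#'
#' @param position 0-based position in the read.
#' @param history integer vector of the preceding binned symbol indices
#'   (most recent last; shorter histories are implicitly zero-padded, as at
#'   a read start).
#' @param quality mode, one of \code{"96"}, \code{"8"}, \code{"4"},
#'   \code{"2"}.
#' @return numeric context id.
#' @export
qualityContextId <- function(position, history = integer(),
                             quality = "8") {
  mode <- .qualModeCode(quality)
  if (mode == 4L) stop("quality mode 'none' has no contexts")
  cppQualContextId(as.integer(position), as.integer(history), mode)
}
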