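#' Simulate a random genome
#'
#' Bases drawn i.i.d. uniform over A, C, G, T.
#'
#' @param length genome length in bases (>= 1).
#' @param seed optional integer seed; when given, the draw is performed
#'   under [withr::with_seed()] so the caller's RNG state is untouched and
#'   identical seeds give identical genomes.
#' @return a single ACGT string.
#' @export
simulateGenome <- function(length, seed = NULL) {
  if (!is.numeric(length) || length < 1) stop("length must be >= 1")
  gen <- function() cppSimGenome(length)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate sequencing reads from a genome
#'
#' Emulates an Illumina-style short-read run: reads are placed uniformly on
#' either strand, substitution errors occur at a fixed per-base rate (no
#' indels, matching the short-read error profile), IDs follow
#' \code{"sim.<n> <n> length=<L>"}, and qualities decay linearly with
#' position plus Gaussian noise.  Paired-end mode samples a fragment of
#' Normal(insertMean, insertSd) length (clamped to the read/genome range)
#' and reports its two ends in forward/reverse-complement orientation, with
#' the originating strand chosen at random per fragment.
#'
#' The total number of reads is \code{round(coverage * genomeLength /
#' meanReadLength)}; in paired mode this total is split into half as many
#' pairs, so coverage counts both mates.
#'
#' @param genome ACGT string, e.g. from [simulateGenome()].
#' @param coverage mean per-base sequencing depth.
#' @param readLength single fixed length, or \code{c(min, max)} for uniform
#'   variable lengths.
#' @param errorRate per-base substitution probability.
#' @param paired generate read pairs?
#' @param insertMean,insertSd fragment-size distribution (paired mode).
#' @param qualityStart,qualityDecay,qualityNoiseSd quality profile: mean
#'   score at position 0, linear drop per position, Gaussian noise SD.
#'   Scores are clamped to 2..40.
#' @param seed optional integer seed (see [simulateGenome()]).
#' @return a [FastqRecords-class] object, or for \code{paired = TRUE} a
#'   list with elements \code{first} and \code{second}.
#' @examples
#' g <- simulateGenome(10000, seed = 1)
#' reads <- simulateReads(g, coverage = 5, readLength = 100, seed = 2)
#' length(reads)
#' @export
simulateReads <- function(genome, coverage = 10, readLength = 100,
                          errorRate = 0.001, paired = FALSE,
                          insertMean = 300, insertSd = 30,
                          qualityStart = 38, qualityDecay = 0.05,
                          qualityNoiseSd = 2, seed = NULL) {
  stopifnot(is.character(genome), length(genome) == 1)
  G <- nchar(genome)
  maxL <- max(readLength)
  if (maxL > G) stop("readLength exceeds genome length")
  if (is.null(seed))
    return(.simReads(genome, G, coverage, readLength, errorRate, paired,
                     insertMean, insertSd, qualityStart, qualityDecay,
                     qualityNoiseSd))
  withr::with_seed(seed,
    .simReads(genome, G, coverage, readLength, errorRate, paired,
              insertMean, insertSd, qualityStart, qualityDecay,
              qualityNoiseSd))
}

.simLens <- function(n, readLength) {
  if (length(readLength) == 1) rep.int(as.integer(readLength), n)
  else as.integer(round(runif(n, readLength[1], readLength[2])))
}

.simReads <- function(genome, G, coverage, readLength, errorRate, paired,
                      insertMean, insertSd, qualityStart, qualityDecay,
                      qualityNoiseSd) {
  meanL <- mean(readLength)
  nTotal <- round(coverage * G / meanL)
  simQ <- function(lens) cppSimQualities(lens, qualityStart, qualityDecay,
                                         qualityNoiseSd, 2L, 40L)
  if (!paired) {
    n <- max(0L, as.integer(nTotal))
    lens <- .simLens(n, readLength)
    starts <- floor(runif(n, 1, G - lens + 1 + 1))  # 1-based, inclusive
    starts <- pmin(starts, G - lens + 1)
    rc <- runif(n) < 0.5
    seqs <- cppExtractReads(genome, starts, lens, rc, errorRate)
    ids <- sprintf("sim.%d %d length=%d", seq_len(n), seq_len(n), lens)
    return(FastqRecords(ids, seqs, simQ(lens), validate = FALSE))
  }
  n <- max(0L, as.integer(round(nTotal / 2)))
  len1 <- .simLens(n, readLength)
  len2 <- .simLens(n, readLength)
  minIns <- pmax(len1, len2)
  ins <- pmin(pmax(round(rnorm(n, insertMean, insertSd)), minIns), G)
  fs <- floor(runif(n, 1, G - ins + 1 + 1))  # fragment start
  fs <- pmin(fs, G - ins + 1)
  flip <- runif(n) < 0.5  # which strand the fragment was read from
  s1 <- ifelse(flip, fs + ins - len1, fs)
  s2 <- ifelse(flip, fs, fs + ins - len2)
  seq1 <- cppExtractReads(genome, s1, len1, flip, errorRate)
  seq2 <- cppExtractReads(genome, s2, len2, !flip, errorRate)
  ids <- sprintf("sim.%d %d", seq_len(n), seq_len(n))
  list(first = FastqRecords(paste0(ids, sprintf(" length=%d", len1)), seq1,
                            simQ(len1), validate = FALSE),
       second = FastqRecords(paste0(ids, sprintf(" length=%d", len2)), seq2,
                             simQ(len2), validate = FALSE))
}
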