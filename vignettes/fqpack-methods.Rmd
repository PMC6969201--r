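---
title: "How fqpack compresses FASTQ files: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How fqpack compresses FASTQ files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqpack)
```

# The problem

A FASTQ file from a short-read sequencer holds three interleaved data types
-- base sequences, read identifiers, and per-base quality scores -- each with
its own redundancy structure.  The bases are the interesting part: a run at
20x coverage reads every genome position about twenty times, so almost every
k-mer in a new read has been seen before.  General-purpose compressors cannot
exploit this because the repetitions are scattered genome-wide, not local.
fqpack compresses bases with a prediction-by-partial-matching (PPM) scheme
whose contexts are k-mers held in dictionaries spanning the whole input
processed so far, coupled with an aggressively adaptive rank model and a
range coder.  Decompression replays exactly the same prediction, update, and
correction sequence, so the decoder needs no side information beyond the
archive itself.

# Base model

## Tiered canonical k-mer dictionaries

Four dictionaries $D_e, D_p, D_s, D_b$ hold successor counts for contexts of
$e-1 < p-1 < s-1 < b-1$ bases.  Each k-mer of a processed read (context plus
successor base) is counted once under its *canonical* orientation -- the
lexicographically smaller of the k-mer and its reverse complement -- so reads
from the two strands reinforce the same statistics.  Counts saturate at
$2^{16}-1$; they feed rank ordering and the correction rule, both of which
only need relative magnitudes.

To code the base at position $i$, the cascade queries the largest tier whose
context fits in the processed prefix, allowing up to two unknown leading
symbols early in a read (a partial query sums the $4^m$ completions).  The
first tier returning a non-zero count vector answers; if all usable tiers
are zero the smallest one answers with zeros, and with fewer than $e-1$
history symbols -- or an N inside every candidate context -- an order-0
per-position model takes over.

Tier sizes derive from the declared genome size $G$ as
$b = \min(32, \max(13, \lceil \log_4 G \rceil + 6))$, $s = b-3$,
$p = \min(16, s-3)$, $e = \max(4, p-4)$.  The intent is that a $(b-1)$-mer
context is with high probability unique in the genome (hence $\log_4 G$ plus
a margin), while $e$ stays small enough to answer very early read positions.
There is no single canonical mapping from genome size to context lengths;
this formula is the package's own choice, all four sizes can be overridden
(`tierSizes =`), and the worked examples use the illustration sizes
4, 6, 9, 12.  $p \le 16$ keeps a packed prefix within 32 bits.

## Rank transform and the adaptive rank model

The four successor counts reorder the alphabet by descending count (ties
lexicographic, N fixed at rank 4), and the *rank* of the actual base is
coded rather than the base itself.  Rank 0 dominates regardless of which
base dominates a context, which concentrates probability mass.

Rank frequencies live in a dense table indexed by a context descriptor:
answering tier (5 values), position bucket ($\min(\text{pos}, 15)$, 4 bits),
the top count quantized into 6 levels, the second/top ratio quantized into 4
levels, and a flag saying whether the previous base was corrected --
$2^{13}$ contexts of 5 counters.  Positions past 15 share one bucket: by
then the answering tier and count pattern carry far more information than
the exact offset.  Each context starts at $(16, 8, 4, 2, 1)$, adds 32 to
the observed rank, and halves everything (floor 1) when the sum passes
$2^{16}$.  These constants make the model shift most of its probability
after a single observation -- the dynamic-Markov-coder-style "learn fast"
behaviour that suits near-deterministic genomic contexts, where classical
PPM estimators would waste many reads converging.  One observation at least
triples the odds of its rank from a fresh table; the tests assert exactly
that.

## Range coder

All streams go through one byte-oriented range coder: 32-bit range, 64-bit
low accumulator with carry propagation through a cached byte run, and byte
renormalization whenever the range drops below $2^{24}$.  Totals are capped
at $2^{24}$ so the integer division stays exact.  On a million i.i.d.
symbols the output is within 0.1% of the Shannon bound plus a constant tail
(asserted in the tests); the flush emits five bytes, so even an empty stream
costs a fixed, small amount.

## In-stream error correction

A sequencing error creates k-mers never seen again, which would bloat the
dictionaries and poison contexts for the rest of the read.  When the b tier
supplied the prediction and the coded base has count 0 while some other base
has a unique count of at least 3, the base is assumed erroneous: it is
*encoded* as-is (losslessness is untouched) but *replaced* in the working
copy that forms subsequent contexts and is inserted into the dictionaries.
The decoder applies the identical rule to identical counts, so both sides'
dictionaries stay byte-identical -- verified block-by-block through state
digests.  At most 8 corrections are applied per read; the cap bounds drift
on pathological reads, and no second-chance correction pass is attempted.
Corrections from tiers below b are not attempted either: shorter contexts
recur by chance and would over-trigger the rule.

## Reordered mode and prefix deltas

In REO mode reads are first sorted lexicographically by sequence (stable, by
the first mate in paired mode), making order part of the loss but leaving
the content multiset intact.  Consecutive sorted reads share prefixes, so
the first $p$ bases pack into a $2p$-bit integer (A=00, C=01, G=10, T=11,
big-endian; `packPrefix("ATACCG")` is 790) and only the difference from the
previous read's packed prefix is coded, as a bit-length symbol plus raw
bits.  Sorting guarantees non-negative deltas; the encoder treats a negative
delta as an internal error.  Reads shorter than $p$ or with an N in the
prefix take an escape flag and order-0 literal coding.  The remainder of the
read is coded exactly as in OO mode.

## Paired-end prediction

The second read of a pair overlaps the first read's genomic neighbourhood,
so a dictionary $M_b$ maps the first read's minimizer (smallest canonical
$(b-2)$-mer over all N-free windows, leftmost tie) to the b-length
minimizers of second reads seen with it -- a counted list sorted by
descending count, capped at 8 candidates, evicting the lowest-count entry
when full.  At coding time the candidates are scanned in rank order for a
verbatim occurrence (either orientation) in the second read; on a hit only
the candidate's rank, its 0-based position, and an orientation bit are
coded, and the covered b bases are skipped by the base coder while still
feeding its contexts.  On a miss the read is coded like a single-end read.
Both sides then record the pair's minimizers, keeping $M_b$ synchronized.

# Identifiers and qualities

IDs in lossless mode are tokenized into maximal alphanumeric runs with all
separators preserved.  Digit runs without leading zeros (and at most 18
digits) are numeric tokens coded as zigzag deltas against the previous ID's
corresponding token; other tokens are compared as strings (equal flag, or a
character-by-character comparison); any structural change falls back to a
literal byte coding of the whole ID.  The first ID of each block is always
literal, keeping blocks self-contained.  Instrument mode keeps only the
first token, coded through a move-to-front list of names; discard mode
stores nothing and the decompressor regenerates `r1`, `r2`, ....

Qualities support five resolutions: 96 (lossless), 8 (the de-facto Illumina
8-level bins with representatives 0, 6, 15, 22, 27, 33, 37, 40), 4, 2, and
none (decoder emits a constant 'I', i.e. Q40).  Binning is idempotent, and
when the input already holds no more distinct scores than the target
alphabet the compressor switches to an identity table, so already-reduced
files round-trip losslessly; the table in force is stored in the archive
header.  Each (binned) score is coded under an adaptive table selected by
read position (64 buckets at full resolution, 16 otherwise) and the previous
2/6/9/10 scores for alphabets 96/8/4/2, packed radix-alphabet.  All four
context spaces fit exactly within $2^{22}$ contexts (e.g. $16 \cdot 8^6 =
2^{22}$), so contexts are direct-indexed and injective -- no hash folding.

# Container

Archives are a little-endian "FQPK" container: a self-describing header
(mode flags, genome size, tier sizes, quality table, per-block stream
sizes and checksums) followed by six entropy streams per 16 MiB block
(bases, lengths, IDs, qualities, pair prediction, prefixes).  Dictionaries
and models persist across blocks -- continuous single-threaded updates give
the best compression ratio -- but block boundaries stay in the format so a
future parallel implementation could merge dictionaries at synchronization
points without a format change.  Each block
carries an FNV-1a checksum of the expected decoded content; decompression
verifies it and reports the offending block on mismatch.

# Synthetic data generator

`simulateGenome()` / `simulateReads()` emulate the data the codec targets:
a uniform random genome; reads placed uniformly on both strands;
substitution errors at a fixed per-base rate (no indels -- the short-read
error profile); Illumina-like IDs `sim.<n> <n> length=<L>`; qualities
decaying linearly with position plus Gaussian noise, clamped to 2..40
(defaults: start 38, slope 0.05/base, SD 2 -- a typical late-cycle decline);
paired fragments of Normal(300, 30) length read from a random strand.  What
this does *not* model: indels, adapter contamination, PCR duplicates,
coverage bias, diploid variation, and realistic position-dependent error
spectra.  Passing round-trips on this generator therefore demonstrate
losslessness and model synchrony, and give realistic *relative* compression
behaviour (coverage scaling, reordering gain), but absolute ratios on real
instruments will differ.

The test suite exercises genomes of 10-200 kbp at 2-30x coverage with
substitution rates up to 1% across all mode combinations (200 randomized
settings), plus a 100 kbp / 20x setting for the learning-behaviour checks.
These sizes keep every k-mer structure identical in kind to production use
while letting the whole suite run on one CPU in minutes; they are small
genomes, not small-genome approximations of the algorithm.

# Numerical and degenerate-input choices

* Counter saturation (not rescaling) at $2^{16}-1$; only count *order*
  matters downstream.
* Partial queries allow at most 2 missing symbols (16 expansions); deeper
  gaps fall through to a smaller tier.
* Zero-length reads, all-N reads, and empty inputs are all legal; N is
  always codable (rank 4 exists in every table) and never corrected.
* Read lengths are coded as zigzag deltas between consecutive reads, so
  fixed-length files pay almost nothing and variable lengths are first-class.
* Ties: rank ordering and REO sorting are stable; equal-count minimizer-pair
  candidates keep insertion order; equal minimizer windows take the leftmost.
* Lowercase bases are uppercased on input and the `+` line is regenerated
  bare; both normalizations are documented and not reversed.

# Known limitations

* Single-threaded; no streaming decompression of individual blocks (the
  dictionaries are cumulative, so blocks decode in order).
* REO mode loses the original order by design; OO mode is the lossless
  order mode.
* The archive format is this package's own; it does not read archives of
  other FASTQ compressors.
* Memory grows with the number of distinct k-mers (roughly with genome
  size); the declared genome size tunes context lengths, not memory caps.
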