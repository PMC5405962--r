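## Pigeonhole seed-and-extend alignment of short single-end reads.
##
## A read is split into three disjoint k-mers (offsets 0, k, 2k); any
## placement with at most two substitutions leaves at least one seed exact,
## so exact k-mer lookup on both orientations enumerates a candidate set
## guaranteed to contain the true origin. Candidates are extended to a
## full-length Hamming comparison; among placements within the mismatch
## budget, a unique best placement aligns the read, two or more equally good
## placements suppress it, and no placement orphans it.

#' Build an exact k-mer index of the reference
#'
#' Indexes every k-mer of the forward reference strand. The default seed
#' length 12 tiles a 36-nt read into exactly three seeds, the pigeonhole
#' guarantee for a two-mismatch budget.
#'
#' @param genome a [ReferenceGenome-class].
#' @param k seed length in bases.
#' @param readLength read length the index will serve (enforces `3k <=`
#'   `readLength`).
#' @return A [SeedIndex-class].
#' @export
#' @examples
#' idx <- buildIndex(ReferenceGenome("ACGTACGT"), k = 4, readLength = 12)
#' seedHits(idx, "ACGT")
buildIndex <- function(genome, k = 12, readLength = 36) {
  if (k < 1) stop("parameter error: seed length k must be at least 1")
  if (3 * k > readLength)
    stop("parameter error: 3*k must not exceed readLength (k = ", k,
         " breaks the pigeonhole guarantee for 2 mismatches)")
  raw <- cpp_build_index(refSequence(genome, as.character = TRUE), as.integer(k))
  methods::new("SeedIndex", k = as.integer(k),
               genomeLength = genomeLength(genome),
               codes = raw$codes, starts = raw$starts, positions = raw$positions)
}

#' Look up the reference positions of one k-mer
#'
#' @param index a [SeedIndex-class].
#' @param kmer character(1) of length `k` over A/C/G/T.
#' @return Sorted integer vector of 1-based start positions (empty when the
#'   k-mer does not occur).
#' @export
seedHits <- function(index, kmer) {
  if (nchar(kmer) != index@k)
    stop("kmer length must equal the index seed length ", index@k)
  cpp_seed_hits(toupper(kmer), index@codes, index@starts, index@positions)
}

#' Align one read
#'
#' @param read character(1) read sequence.
#' @param index a [SeedIndex-class] of the reference.
#' @param genome the [ReferenceGenome-class] the index was built from.
#' @param maxMismatch mismatch budget (total Hamming mismatches per read).
#' @return A one-row data.frame with columns `read_id`, `status` (`aligned`,
#'   `suppressed` or `orphan`), `position` (leftmost 1-based forward-strand
#'   coordinate; `NA` unless aligned), `strand`, `mismatches`. Reads
#'   containing non-ACGT symbols are triaged as orphans, not errors.
#' @export
alignRead <- function(read, index, genome, maxMismatch = 2) {
  alignReadSet(as.character(read), index, genome, maxMismatch)$alignments
}

#' Align a read set and compute triage statistics
#'
#' Each read is placed by pigeonhole seeding and Hamming extension on both
#' strands. Among placements with at most `maxMismatch` mismatches the read
#' is `aligned` if the minimum-mismatch placement is unique, `suppressed` if
#' two or more placements tie at the minimum (multi-mapped), and `orphan` if
#' no placement is within budget.
#'
#' @param reads a `DNAStringSet` (or character vector) of reads.
#' @param index a [SeedIndex-class].
#' @param genome the [ReferenceGenome-class] the index was built from.
#' @param maxMismatch mismatch budget per read.
#' @param strainId label recorded in the statistics.
#' @return A list with `alignments` (data.frame: `read_id`, `status`,
#'   `position`, `strand`, `mismatches`) and `stats`
#'   ([AlignmentStats-class]).
#' @export
alignReadSet <- function(reads, index, genome, maxMismatch = 2,
                         strainId = "strain") {
  seqs <- as.character(reads)
  ids <- if (!is.null(names(seqs))) names(seqs) else
    sprintf("read_%d", seq_along(seqs))
  if (length(seqs) == 0) {
    aln <- data.frame(read_id = character(0), status = character(0),
                      position = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
    stats <- AlignmentStats(strainId, 0, 0, 0, 0,
                            readLength = NA_real_,
                            genomeLength = genomeLength(genome))
    return(list(alignments = aln, stats = stats))
  }
  res <- cpp_align_reads(refSequence(genome, as.character = TRUE), seqs,
                         index@codes, index@starts, index@positions,
                         index@k, as.integer(maxMismatch))
  status <- c("aligned", "suppressed", "orphan")[res$status]
  aln <- data.frame(read_id = ids, status = status, position = res$position,
                    strand = res$strand, mismatches = res$mismatches,
                    stringsAsFactors = FALSE)
  nBad <- sum(!grepl("^[ACGTacgt]+$", seqs))
  if (nBad > 0)
    message(nBad, " read(s) contained non-ACGT symbols and were counted as orphans")
  stats <- AlignmentStats(strainId,
                          totalReads = length(seqs),
                          alignedReads = sum(status == "aligned"),
                          suppressedReads = sum(status == "suppressed"),
                          orphanReads = sum(status == "orphan"),
                          readLength = nchar(seqs[1]),
                          genomeLength = genomeLength(genome))
  list(alignments = aln, stats = stats)
}

#' Approximate genome-wide fold coverage
#'
#' The coverage identity `alignedReads * readLength / genomeLength`, rounded
#' to the nearest integer fold.
#'
#' @param stats an [AlignmentStats-class], or a numeric count of aligned
#'   reads.
#' @param readLength read length (taken from `stats` when omitted).
#' @param genomeLength genome length (taken from `stats` when omitted).
#' @return integer fold coverage.
#' @export
#' @examples
#' computeDepth(41667, readLength = 36, genomeLength = 50000)  # 30
computeDepth <- function(stats, readLength = NULL, genomeLength = NULL) {
  if (methods::is(stats, "AlignmentStats")) {
    aligned <- stats@alignedReads
    readLength <- readLength %||% stats@readLength
    genomeLength <- genomeLength %||% stats@genomeLength
  } else {
    aligned <- stats
  }
  if (is.null(genomeLength) || is.na(genomeLength) || genomeLength <= 0)
    stop("genomeLength must be positive")
  if (aligned == 0) return(0L)
  as.integer(roundHalfUp(aligned * readLength / genomeLength, 0))
}

#' Tabulate AlignmentStats
#'
#' @param x an [AlignmentStats-class].
#' @param ... ignored.
#' @return A one-row data.frame with counts, percentages (half-up, 2
#'   decimals; `0.00` for an empty read set) and approximate depth.
#' @exportS3Method base::as.data.frame
as.data.frame.AlignmentStats <- function(x, ...) {
  pct <- function(count) {
    if (x@totalReads == 0) return(0)
    roundHalfUp(100 * count / x@totalReads, 2)
  }
  depth <- if (is.na(x@genomeLength) || is.na(x@readLength) ||
               x@totalReads == 0) 0L else computeDepth(x)
  data.frame(strain = x@strainId, total_reads = x@totalReads,
             aligned_reads = x@alignedReads, aligned_pct = pct(x@alignedReads),
             suppressed_reads = x@suppressedReads,
             suppressed_pct = pct(x@suppressedReads),
             orphan_reads = x@orphanReads, orphan_pct = pct(x@orphanReads),
             depth = depth, stringsAsFactors = FALSE)
}

#' @export
setMethod("as.data.frame", "AlignmentStats",
          function(x, ...) as.data.frame.AlignmentStats(x, ...))
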