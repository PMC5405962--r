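## Pileup construction and strict-consensus SNV calling.

#' Build a base pileup from aligned reads
#'
#' Tallies, for every reference position, the base each aligned read places
#' there. Reads aligned to the reverse strand contribute their
#' reverse-complemented bases in reference orientation. Suppressed and
#' orphan reads are excluded.
#'
#' @param alignments alignment data.frame from [alignReadSet()].
#' @param reads the read set the alignments refer to (`DNAStringSet` or
#'   character vector, same order/names as submitted to the aligner).
#' @param genome the [ReferenceGenome-class].
#' @return An integer matrix with rows `A`, `C`, `G`, `T` and one column per
#'   reference position (class `pileup`). `colSums()` of the matrix is the
#'   aligned depth at each position.
#' @export
buildPileup <- function(alignments, reads, genome) {
  keep <- alignments$status == "aligned"
  seqs <- as.character(reads)[keep]
  pos <- alignments$position[keep]
  strand <- alignments$strand[keep]
  counts <- cpp_pileup(genomeLength(genome),
                       if (length(seqs)) seqs else character(0),
                       as.integer(pos), as.character(strand))
  rownames(counts) <- BASES
  class(counts) <- c("pileup", class(counts))
  counts
}

#' Pileup as a per-position table
#'
#' @param pileup matrix from [buildPileup()].
#' @return data.frame with columns `position`, `depth`, `nA`, `nC`, `nG`,
#'   `nT`.
#' @export
pileupTable <- function(pileup) {
  data.frame(position = seq_len(ncol(pileup)), depth = colSums(pileup),
             nA = pileup["A", ], nC = pileup["C", ], nG = pileup["G", ],
             nT = pileup["T", ], row.names = NULL)
}

#' Call SNVs by strict read consensus
#'
#' A variant is called at a position when the aligned depth reaches
#' `minDepth`, the most frequent base differs from the reference, and that
#' base is supported by at least `minFraction` of the aligned reads covering
#' the position. With the default `minFraction = 0.99` this is the
#' "at least 99% of reads agree" criterion; note that at depths below 100
#' it is equivalent to unanimity. Ties for the most frequent base are broken
#' in lexicographic base order (with `minFraction > 0.5` a tie can never
#' reach the support threshold, so the tie-break never creates a call).
#'
#' @param pileup matrix from [buildPileup()].
#' @param genome the [ReferenceGenome-class].
#' @param minFraction minimum supporting-read fraction (`0.5 < f <= 1`).
#' @param minDepth minimum aligned depth.
#' @param strainId strain label stamped on the calls.
#' @return data.frame with columns `strain`, `position`, `ref`, `alt`,
#'   `support_fraction`, `depth`, ordered by position.
#' @export
callSnvs <- function(pileup, genome, minFraction = 0.99, minDepth = 10,
                     strainId = "strain") {
  if (minFraction <= 0.5 || minFraction > 1)
    stop("minFraction must satisfy 0.5 < f <= 1")
  if (ncol(pileup) == 0)
    return(data.frame(strain = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      support_fraction = numeric(0), depth = integer(0)))
  depth <- colSums(pileup)
  top <- max.col(t(pileup), ties.method = "first")  # lexicographic tie-break
  topCount <- pileup[cbind(top, seq_len(ncol(pileup)))]
  topBase <- BASES[top]
  refChars <- strsplit(refSequence(genome, as.character = TRUE), "")[[1]]
  # small epsilon guards against floating-point representation of exact
  # decimal fractions (e.g. 99/100 vs the literal 0.99)
  support <- topCount / pmax(depth, 1)
  callable <- depth >= pmax(minDepth, 1) & topBase != refChars &
    support >= minFraction - 1e-12
  idx <- which(callable)
  data.frame(strain = rep(strainId, length(idx)), position = idx,
             ref = refChars[idx],
             alt = topBase[idx], support_fraction = support[idx],
             depth = as.integer(depth[idx]), row.names = NULL,
             stringsAsFactors = FALSE)
}
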