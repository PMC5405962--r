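#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib suppressorSeq, .registration = TRUE
NULL

#' Reference genome container
#'
#' A single circular-treated linear chromosome, stored as a
#' [Biostrings::DNAString] restricted to the A/C/G/T alphabet.
#'
#' @slot id character(1), sequence label (used as CHROM/@SQ name in outputs).
#' @slot sequence a `DNAString` over \{A,C,G,T\}.
#' @exportClass ReferenceGenome
setClass("ReferenceGenome",
  representation(id = "character", sequence = "ANY"),
  validity = function(object) {
    if (length(object@id) != 1L || !nzchar(object@id))
      return("'id' must be a single non-empty string")
    if (!methods::is(object@sequence, "DNAString"))
      return("'sequence' must be a DNAString")
    freq <- Biostrings::alphabetFrequency(object@sequence)
    if (sum(freq[c("A", "C", "G", "T")]) != length(object@sequence))
      return("sequence alphabet must be restricted to A/C/G/T")
    TRUE
  }
)

#' Construct a ReferenceGenome
#'
#' @param sequence character(1) or `DNAString` over A/C/G/T.
#' @param id sequence label.
#' @return A [ReferenceGenome-class] object.
#' @export
#' @examples
#' ReferenceGenome("ACGTACGT", id = "toy")
ReferenceGenome <- function(sequence, id = "chr") {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  methods::new("ReferenceGenome", id = id, sequence = sequence)
}

#' @describeIn ReferenceGenome-class genome length in bases.
#' @param x,object a `ReferenceGenome`.
#' @export
setMethod("length", "ReferenceGenome", function(x) length(x@sequence))

#' Genome length accessor
#' @param x a [ReferenceGenome-class].
#' @return integer(1) number of bases.
#' @export
genomeLength <- function(x) length(x@sequence)

#' Genome sequence accessor
#' @param x a [ReferenceGenome-class].
#' @param as.character return a plain string instead of a `DNAString`.
#' @return the genome sequence.
#' @export
refSequence <- function(x, as.character = FALSE) {
  if (as.character) as.character(x@sequence) else x@sequence
}

#' Genome id accessor
#' @param x a [ReferenceGenome-class].
#' @return character(1) label.
#' @export
refId <- function(x) x@id

setMethod("show", "ReferenceGenome", function(object) {
  cat("ReferenceGenome '", object@id, "': ", length(object@sequence),
      " bp\n", sep = "")
})

#' Exact k-mer index of a reference genome
#'
#' Maps every length-`k` substring of the forward reference to the sorted list
#' of its 1-based start positions. Backed by a sorted code table queried by
#' binary search; see [buildIndex()] and [seedHits()].
#'
#' @slot k seed length in bases.
#' @slot genomeLength reference length in bases.
#' @slot codes numeric, sorted distinct 2-bit k-mer codes.
#' @slot starts integer, offsets delimiting each code's position run.
#' @slot positions integer, 1-based start positions grouped by code.
#' @exportClass SeedIndex
setClass("SeedIndex",
  representation(k = "integer", genomeLength = "integer",
                 codes = "numeric", starts = "integer", positions = "integer"),
  validity = function(object) {
    n <- object@genomeLength - object@k + 1L
    if (length(object@positions) != n)
      return(sprintf("index must hold exactly L - k + 1 = %d positions", n))
    TRUE
  }
)

setMethod("show", "SeedIndex", function(object) {
  cat("SeedIndex: k =", object@k, "over", object@genomeLength, "bp (",
      length(object@codes), "distinct k-mers )\n")
})

#' Read-triage statistics for one strain's alignment
#'
#' Counts of aligned, suppressed (multi-mapped) and orphan (unalignable)
#' reads, with percentage and fold-coverage accessors. The three counts
#' always sum to the total.
#'
#' @slot strainId strain label.
#' @slot totalReads,alignedReads,suppressedReads,orphanReads numeric counts.
#' @slot readLength,genomeLength numeric, used for the depth identity.
#' @exportClass AlignmentStats
setClass("AlignmentStats",
  representation(strainId = "character", totalReads = "numeric",
                 alignedReads = "numeric", suppressedReads = "numeric",
                 orphanReads = "numeric", readLength = "numeric",
                 genomeLength = "numeric"),
  validity = function(object) {
    if (object@alignedReads + object@suppressedReads + object@orphanReads !=
        object@totalReads)
      return("aligned + suppressed + orphan must equal total")
    if (any(c(object@totalReads, object@alignedReads, object@suppressedReads,
              object@orphanReads) < 0))
      return("read counts must be non-negative")
    TRUE
  }
)

#' Construct AlignmentStats
#'
#' @param strainId strain label.
#' @param totalReads,alignedReads,suppressedReads,orphanReads read counts;
#'   the last three must sum to `totalReads`.
#' @param readLength read length in bases.
#' @param genomeLength reference length in bases.
#' @return An [AlignmentStats-class] object.
#' @export
AlignmentStats <- function(strainId, totalReads, alignedReads,
                           suppressedReads, orphanReads,
                           readLength = 36, genomeLength = NA_real_) {
  methods::new("AlignmentStats", strainId = as.character(strainId),
               totalReads = as.numeric(totalReads),
               alignedReads = as.numeric(alignedReads),
               suppressedReads = as.numeric(suppressedReads),
               orphanReads = as.numeric(orphanReads),
               readLength = as.numeric(readLength),
               genomeLength = as.numeric(genomeLength))
}

setMethod("show", "AlignmentStats", function(object) {
  df <- as.data.frame(object)
  cat("AlignmentStats for", object@strainId, "\n")
  print(df, row.names = FALSE)
})

#' Simulation configuration
#'
#' Parameters of the synthetic resequencing experiment: toy genome size and
#' feature content, strain count, read length, target fold coverage and the
#' per-base substitution-error rate of the sequencer model.
#'
#' @slot genomeLength genome size in bases.
#' @slot geneCount number of protein-coding genes.
#' @slot trnaCount number of tRNA genes (at least one carries anticodon CGA).
#' @slot nStrains number of suppressor strains simulated.
#' @slot readLength read length in bases (36 by default).
#' @slot meanDepth target fold coverage of each strain.
#' @slot errorRate per-base substitution probability in simulated reads.
#' @slot seed master integer seed; per-strain sub-seeds are `seed + strain index`.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(genomeLength = "integer", geneCount = "integer",
                 trnaCount = "integer", nStrains = "integer",
                 readLength = "integer", meanDepth = "numeric",
                 errorRate = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@readLength > object@genomeLength)
      return("readLength must not exceed genomeLength")
    if (object@errorRate < 0 || object@errorRate >= 0.25)
      return("errorRate must satisfy 0 <= errorRate < 0.25")
    if (object@meanDepth <= 0) return("meanDepth must be positive")
    if (object@genomeLength < 1L) return("genomeLength must be positive")
    TRUE
  }
)

#' Construct a SimulationConfig
#'
#' @param genomeLength genome size in bases.
#' @param geneCount number of CDS features.
#' @param trnaCount number of tRNA features.
#' @param nStrains number of strains.
#' @param readLength read length in bases.
#' @param meanDepth target fold coverage.
#' @param errorRate per-base substitution probability (`0 <= e < 0.25`).
#' @param seed master integer seed.
#' @return A [SimulationConfig-class] object.
#' @export
#' @examples
#' SimulationConfig(genomeLength = 50000, geneCount = 20, trnaCount = 1,
#'                  nStrains = 13, meanDepth = 30, errorRate = 0.003, seed = 1)
SimulationConfig <- function(genomeLength, geneCount, trnaCount, nStrains = 1,
                             readLength = 36, meanDepth = 30,
                             errorRate = 0.003, seed = 0) {
  methods::new("SimulationConfig", genomeLength = as.integer(genomeLength),
               geneCount = as.integer(geneCount), trnaCount = as.integer(trnaCount),
               nStrains = as.integer(nStrains), readLength = as.integer(readLength),
               meanDepth = as.numeric(meanDepth), errorRate = as.numeric(errorRate),
               seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@genomeLength, "bp,", object@geneCount,
      "CDS +", object@trnaCount, "tRNA,", object@nStrains, "strains,",
      object@readLength, "nt reads at", object@meanDepth,
      "X, error", object@errorRate, ", seed", object@seed, "\n")
})

#' Full pipeline configuration
#'
#' Extends [SimulationConfig-class] with the variant specifications to
#' implant, aligner parameters and caller thresholds.
#'
#' @slot sharedSpec character vector of intended effects for the shared
#'   (parental) SNVs, one per variant.
#' @slot uniqueSpec data.frame with one row per strain: `strain`, `kind`
#'   (SNV or DEL), `effect`, `essential` (logical; constrains the target gene).
#' @slot seedLength aligner seed (k-mer) length.
#' @slot maxMismatch maximum Hamming mismatches for an accepted placement.
#' @slot minFraction consensus threshold: minimum supporting-read fraction.
#' @slot minDepth minimum aligned depth required to call a variant.
#' @slot delLength length in bases of implanted private deletions.
#' @exportClass PipelineConfig
setClass("PipelineConfig", contains = "SimulationConfig",
  representation(sharedSpec = "character", uniqueSpec = "data.frame",
                 seedLength = "integer", maxMismatch = "integer",
                 minFraction = "numeric", minDepth = "integer",
                 delLength = "integer"),
  validity = function(object) {
    if (object@minFraction <= 0.5 || object@minFraction > 1)
      return("minFraction must satisfy 0.5 < f <= 1")
    if (nrow(object@uniqueSpec) > 0 &&
        !all(c("strain", "kind", "effect") %in% names(object@uniqueSpec)))
      return("uniqueSpec needs columns strain, kind, effect")
    if (nrow(object@uniqueSpec) != object@nStrains)
      return("uniqueSpec must have one row per strain")
    if (anyDuplicated(object@uniqueSpec$strain))
      return("at most one unique variant per strain")
    if (3L * object@seedLength > object@readLength)
      return("seedLength must satisfy 3*k <= readLength (pigeonhole)")
    TRUE
  }
)

#' Construct a PipelineConfig
#'
#' @inheritParams SimulationConfig
#' @param sharedSpec character vector of intended shared-variant effects
#'   (values among `intergenic`, `synonymous`, `missense`, `stop_gain`,
#'   `stop_gain_amber`, `anticodon`).
#' @param uniqueSpec data.frame (`strain`, `kind`, `effect`, optional
#'   `essential`), one row per strain. `kind` is `"SNV"` or `"DEL"`.
#' @param seedLength aligner k-mer seed length.
#' @param maxMismatch mismatch budget per read.
#' @param minFraction consensus support threshold for calling.
#' @param minDepth depth floor for calling.
#' @param delLength implanted deletion length (bases).
#' @return A [PipelineConfig-class] object.
#' @export
PipelineConfig <- function(genomeLength, geneCount, trnaCount, nStrains,
                           sharedSpec, uniqueSpec, readLength = 36,
                           meanDepth = 30, errorRate = 0.003, seed = 0,
                           seedLength = 12, maxMismatch = 2,
                           minFraction = 0.99, minDepth = 10, delLength = 3) {
  if (!"essential" %in% names(uniqueSpec)) uniqueSpec$essential <- NA
  methods::new("PipelineConfig", genomeLength = as.integer(genomeLength),
               geneCount = as.integer(geneCount), trnaCount = as.integer(trnaCount),
               nStrains = as.integer(nStrains), readLength = as.integer(readLength),
               meanDepth = as.numeric(meanDepth), errorRate = as.numeric(errorRate),
               seed = as.integer(seed), sharedSpec = as.character(sharedSpec),
               uniqueSpec = uniqueSpec, seedLength = as.integer(seedLength),
               maxMismatch = as.integer(maxMismatch),
               minFraction = as.numeric(minFraction),
               minDepth = as.integer(minDepth), delLength = as.integer(delLength))
}

setMethod("show", "PipelineConfig", function(object) {
  methods::callNextMethod()
  cat("  shared variants:", length(object@sharedSpec),
      "| caller: fraction >=", object@minFraction, ", depth >=",
      object@minDepth, "| aligner: k =", object@seedLength, ", <=",
      object@maxMismatch, "mismatches\n")
})

#' Variant-by-strain incidence matrix
#'
#' Rows are distinct variant keys `(position, ref, alt)`, columns are strains;
#' a cell is `TRUE` when that strain's call set contains the key.
#'
#' @slot keys data.frame with columns `position`, `ref`, `alt`.
#' @slot strains character vector of strain ids.
#' @slot presence logical matrix, `nrow(keys)` by `length(strains)`.
#' @exportClass VariantMatrix
setClass("VariantMatrix",
  representation(keys = "data.frame", strains = "character",
                 presence = "matrix"),
  validity = function(object) {
    if (nrow(object@presence) != nrow(object@keys) ||
        ncol(object@presence) != length(object@strains))
      return("presence matrix dimensions must match keys x strains")
    if (anyDuplicated(paste(object@keys$position, object@keys$ref,
                            object@keys$alt)))
      return("variant keys must be unique")
    TRUE
  }
)

setMethod("show", "VariantMatrix", function(object) {
  cat("VariantMatrix:", nrow(object@keys), "variant keys x",
      length(object@strains), "strains\n")
})

#' Variant keys accessor
#' @param x a [VariantMatrix-class].
#' @return data.frame of `(position, ref, alt)` keys.
#' @export
variantKeys <- function(x) x@keys

#' Presence matrix accessor
#' @param x a [VariantMatrix-class].
#' @return logical incidence matrix (variants x strains).
#' @export
presenceMatrix <- function(x) {
  m <- x@presence
  dimnames(m) <- list(NULL, x@strains)
  m
}

#' Strain ids of a VariantMatrix
#' @param x a [VariantMatrix-class].
#' @return character vector of strain ids.
#' @export
strainIds <- function(x) x@strains
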