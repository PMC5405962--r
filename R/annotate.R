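## Protein-level effect annotation: feature localization, codon effects,
## tRNA anticodon effects and amber-suppressor readthrough.
##
## Notation follows resequencing-table conventions rather than HGVS:
## "L36Q" (missense), "E38E" (synonymous), "W286Stop" (premature stop),
## and, for amber stop gains in essential genes, "Q176Amber" with the
## suffix "(S)" added when the strain's suppressor tRNA reads the amber
## codon through as serine ("Q176Amber(S)").

#' Locate a position against the feature table
#'
#' @param position 1-based genome coordinate.
#' @param features feature `GRanges`.
#' @param genome the [ReferenceGenome-class] (bounds check).
#' @return A list with `context` (`"CDS"`, `"tRNA"` or `"intergenic"`) and
#'   `feature` (the covering `GRanges` row, or `NULL` when intergenic).
#' @export
locateFeature <- function(position, features, genome) {
  if (position < 1 || position > genomeLength(genome))
    stop("position out of genome bounds")
  if (length(features) == 0)
    return(list(context = "intergenic", feature = NULL))
  q <- GenomicRanges::GRanges(S4Vectors::runValue(GenomicRanges::seqnames(features))[1] %||% "chr",
                              IRanges::IRanges(position, position))
  hits <- GenomicRanges::findOverlaps(q, features, ignore.strand = TRUE)
  idx <- S4Vectors::subjectHits(hits)
  if (length(idx) == 0)
    return(list(context = "intergenic", feature = NULL))
  if (length(idx) > 1)
    stop("annotation-model error: overlapping features cover position ", position)
  list(context = S4Vectors::mcols(features)$kind[idx], feature = features[idx])
}

#' Annotate the codon effect of a coding SNV
#'
#' Obtains the coding-strand sequence (reverse-complemented for minus-strand
#' genes), translates the reference and mutated codons with the standard
#' bacterial genetic code and derives the effect class and protein notation.
#' Stop gains are subtyped by the created stop codon: TAG = amber,
#' TAA = ochre, TGA = opal.
#'
#' @param position,ref,alt SNV on the forward genome strand (single bases).
#' @param feature the covering CDS (`GRanges` row).
#' @param genome the [ReferenceGenome-class].
#' @return One-row data.frame: `position`, `ref`, `alt`, `context`, `gene`,
#'   `codon_number`, `ref_aa`, `alt_aa`, `effect_class`, `notation`,
#'   `readthrough_applied`.
#' @export
codonEffect <- function(position, ref, alt, feature, genome) {
  seqChr <- refSequence(genome, as.character = TRUE)
  if (substr(seqChr, position, position) != ref)
    stop("consistency error: reference allele mismatch at position ", position)
  st <- GenomicRanges::start(feature); en <- GenomicRanges::end(feature)
  minus <- as.character(GenomicRanges::strand(feature)) == "-"
  cds <- substr(seqChr, st, en)
  if (minus) cds <- revComp(cds)
  offset <- if (minus) en - position + 1L else position - st + 1L
  codonNumber <- ceiling(offset / 3)
  posInCodon <- (offset - 1L) %% 3L + 1L
  codon <- substr(cds, 3L * codonNumber - 2L, 3L * codonNumber)
  codingAlt <- if (minus) unname(complementBase(alt)) else alt
  newCodon <- replaceAt(codon, posInCodon, codingAlt)
  refAa <- translateCodon(codon)
  altAa <- translateCodon(newCodon)
  md <- S4Vectors::mcols(feature)
  if (altAa == refAa) {
    cls <- "synonymous"
    notation <- paste0(aaSymbol(refAa), codonNumber, aaSymbol(altAa))
  } else if (altAa == "*") {
    cls <- unname(STOP_CODONS[newCodon])
    # essential-gene amber stops are written "Amber": whether they are
    # tolerated at all hinges on suppressor-tRNA readthrough
    stopWord <- if (cls == "stop_gain_amber" && isTRUE(md$essential)) "Amber"
                else "Stop"
    notation <- paste0(aaSymbol(refAa), codonNumber, stopWord)
  } else {
    cls <- "missense"
    notation <- paste0(aaSymbol(refAa), codonNumber, aaSymbol(altAa))
  }
  data.frame(position = position, ref = ref, alt = alt, context = "CDS",
             gene = md$gene_name, codon_number = codonNumber,
             ref_aa = aaSymbol(refAa), alt_aa = aaSymbol(altAa),
             effect_class = cls, notation = notation,
             readthrough_applied = FALSE, stringsAsFactors = FALSE)
}

#' Annotate a tRNA variant
#'
#' Variants inside the anticodon triplet are classified as
#' `anticodon_change`; the CGA to CTA change that lets the serine tRNA pair
#' with the TAG amber stop codon additionally sets the `amber_suppressor`
#' flag. Variants in the tRNA body outside the anticodon are
#' anticodon-neutral (`trna_body`).
#'
#' @param position,ref,alt SNV on the forward genome strand.
#' @param feature the covering tRNA (`GRanges` row).
#' @param genome the [ReferenceGenome-class].
#' @return One-row data.frame as for [codonEffect()] plus an
#'   `amber_suppressor` logical column.
#' @export
anticodonEffect <- function(position, ref, alt, feature, genome) {
  seqChr <- refSequence(genome, as.character = TRUE)
  if (substr(seqChr, position, position) != ref)
    stop("consistency error: reference allele mismatch at position ", position)
  md <- S4Vectors::mcols(feature)
  st <- GenomicRanges::start(feature)
  acStart <- st + md$anticodon_offset  # anticodon stored in forward orientation
  base <- function(cls, notation, suppressor) {
    data.frame(position = position, ref = ref, alt = alt, context = "tRNA",
               gene = md$gene_name, codon_number = NA_integer_,
               ref_aa = NA_character_, alt_aa = NA_character_,
               effect_class = cls, notation = notation,
               readthrough_applied = FALSE, amber_suppressor = suppressor,
               stringsAsFactors = FALSE)
  }
  if (position < acStart || position > acStart + 2L)
    return(base("trna_body", "-", FALSE))
  anticodon <- substr(seqChr, acStart, acStart + 2L)
  newAnticodon <- replaceAt(anticodon, position - acStart + 1L, alt)
  # only CTA (read 3'->5' against the codon) pairs the TAG amber stop
  suppressor <- anticodon == "CGA" && newAnticodon == "CTA"
  base("anticodon_change", paste0(anticodon, ">", newAnticodon), suppressor)
}

#' Annotate one variant key
#'
#' Dispatches on feature context: [codonEffect()] in CDS, [anticodonEffect()]
#' in tRNA, or an intergenic annotation.
#'
#' @param position,ref,alt SNV key on the forward genome strand.
#' @param features feature `GRanges`.
#' @param genome the [ReferenceGenome-class].
#' @return One-row annotation data.frame (see [codonEffect()]); intergenic
#'   variants have `gene = "-"`, `notation = "-"` and
#'   `effect_class = "intergenic"`.
#' @export
annotateVariant <- function(position, ref, alt, features, genome) {
  loc <- locateFeature(position, features, genome)
  if (loc$context == "intergenic") {
    return(data.frame(position = position, ref = ref, alt = alt,
                      context = "intergenic", gene = "-",
                      codon_number = NA_integer_, ref_aa = NA_character_,
                      alt_aa = NA_character_, effect_class = "intergenic",
                      notation = "-", readthrough_applied = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (loc$context == "tRNA") {
    out <- anticodonEffect(position, ref, alt, loc$feature, genome)
    out$amber_suppressor <- NULL
    return(out)
  }
  codonEffect(position, ref, alt, loc$feature, genome)
}

#' Annotate a set of variant keys
#'
#' @param keys data.frame with columns `position`, `ref`, `alt`.
#' @param features feature `GRanges`.
#' @param genome the [ReferenceGenome-class].
#' @return data.frame with one annotation row per key.
#' @export
annotateVariants <- function(keys, features, genome) {
  if (nrow(keys) == 0)
    return(annotateVariant(1, substr(refSequence(genome, TRUE), 1, 1),
                           "A", features, genome)[0, ])
  do.call(rbind, lapply(seq_len(nrow(keys)), function(i)
    annotateVariant(keys$position[i], keys$ref[i], keys$alt[i],
                    features, genome)))
}

#' Derive a strain's amber-suppressor status from its call set
#'
#' A strain is an amber suppressor iff its full call set (parental plus
#' unique variants) contains a tRNA anticodon change CGA to CTA.
#'
#' @param strainCalls data.frame of the strain's calls (`position`, `ref`,
#'   `alt`).
#' @param features feature `GRanges`.
#' @param genome the [ReferenceGenome-class].
#' @return A list with `strain_id` and logical `amber_suppressor`.
#' @export
strainContext <- function(strainCalls, features, genome) {
  suppressor <- FALSE
  for (i in seq_len(nrow(strainCalls))) {
    loc <- locateFeature(strainCalls$position[i], features, genome)
    if (loc$context != "tRNA") next
    eff <- anticodonEffect(strainCalls$position[i], strainCalls$ref[i],
                           strainCalls$alt[i], loc$feature, genome)
    if (isTRUE(eff$amber_suppressor)) suppressor <- TRUE
  }
  list(strain_id = unique(strainCalls$strain) %||% NA_character_,
       amber_suppressor = suppressor)
}

#' Apply amber-suppressor readthrough to stop-gain annotations
#'
#' In an amber-suppressor strain, every amber stop gain in an essential gene
#' is annotated as read through by serine misincorporation: the notation
#' gains the suffix `"(S)"` and `readthrough_applied` is set. Ochre and
#' opal stop gains are never modified, nor is anything in a non-suppressor
#' strain.
#'
#' @param effects annotation data.frame from [annotateVariants()].
#' @param context strain context from [strainContext()].
#' @param features feature `GRanges` (essentiality lookup).
#' @return The annotation data.frame with readthrough applied.
#' @export
applyReadthrough <- function(effects, context, features) {
  if (!isTRUE(context$amber_suppressor) || nrow(effects) == 0) return(effects)
  md <- S4Vectors::mcols(features)
  essentialGenes <- md$gene_name[md$kind == "CDS" & md$essential]
  hit <- effects$effect_class == "stop_gain_amber" &
    effects$gene %in% essentialGenes & !effects$readthrough_applied
  effects$notation[hit] <- paste0(effects$notation[hit], "(S)")
  effects$readthrough_applied[hit] <- TRUE
  effects
}
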