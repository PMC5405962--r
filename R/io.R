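## Readers and writers for the standard on-disk artifacts. FASTA/FASTQ go
## through Biostrings, GFF3 through rtracklayer; the simple tabular and
## record formats (TSV, VCF, SAM) are emitted directly.

#' Write / read the reference genome as FASTA
#'
#' @param genome a [ReferenceGenome-class].
#' @param path output file.
#' @return `writeReferenceFasta` the path invisibly; `readReferenceFasta`
#'   a [ReferenceGenome-class].
#' @export
writeReferenceFasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(refSequence(genome))
  names(x) <- refId(genome)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname writeReferenceFasta
#' @export
readReferenceFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ReferenceGenome(as.character(x[[1]]), id = sub("\\s.*", "", names(x)[1]))
}

#' Write / read the feature table as GFF3
#'
#' Features are written 1-based inclusive with types `CDS` and `tRNA` and
#' attributes `ID`, `gene_name`, `product`, `essential` (`true`/`false`) and,
#' for tRNAs, `anticodon_offset`.
#'
#' @param features feature `GRanges`.
#' @param path output file.
#' @return `writeFeaturesGff3` the path invisibly; `readFeaturesGff3` the
#'   feature `GRanges`.
#' @export
writeFeaturesGff3 <- function(features, path) {
  g <- features
  md <- S4Vectors::mcols(g)
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    source = "suppressorSeq", type = md$kind,
    phase = ifelse(md$kind == "CDS", 0L, NA_integer_),
    ID = md$feature_id, gene_name = md$gene_name, product = md$product,
    essential = ifelse(md$essential, "true", "false"),
    anticodon_offset = md$anticodon_offset)
  rtracklayer::export(g, path, format = "gff3")
  invisible(path)
}

#' @rdname writeFeaturesGff3
#' @export
readFeaturesGff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(g)
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    feature_id = md$ID, kind = as.character(md$type),
    gene_name = md$gene_name, product = md$product,
    essential = md$essential == "true",
    anticodon_offset = suppressWarnings(as.integer(md$anticodon_offset)))
  g
}

#' Write / read simulated reads as 4-line FASTQ
#'
#' Qualities are constant (`I`, Phred 40): the simulator's error model is
#' uniform and quality-blind, as is the aligner.
#'
#' @param reads `DNAStringSet` of reads.
#' @param path output file.
#' @return `writeReadsFastq` the path invisibly; `readReadsFastq` a named
#'   `DNAStringSet`.
#' @export
writeReadsFastq <- function(reads, path) {
  Biostrings::writeXStringSet(reads, filepath = path, format = "fastq")
  invisible(path)
}

#' @rdname writeReadsFastq
#' @export
readReadsFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write / read the simulation truth table as TSV
#'
#' Columns: `strain`, `position`, `ref`, `alt`, `kind`, `class`, `effect`.
#'
#' @param truth truth data.frame from [implantVariants()].
#' @param path output file.
#' @return `writeTruthTsv` the path invisibly; `readTruthTsv` a data.frame.
#' @export
writeTruthTsv <- function(truth, path) {
  utils::write.table(truth[, c("strain", "position", "ref", "alt", "kind",
                               "class", "effect")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthTsv
#' @export
readTruthTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(position = "integer"))
}

#' Write per-strain alignment statistics as TSV
#'
#' One row per strain with counts, percentages (2 decimals, trailing `%`)
#' and approximate fold coverage, mirroring the conventional read-statistics
#' table of a resequencing study.
#'
#' @param statsList list of [AlignmentStats-class] objects.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeStatsTsv <- function(statsList, path) {
  utils::write.table(renderStatsTable(statsList), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write single-strain SNV calls as VCF 4.2
#'
#' INFO fields: `DP` (aligned depth) and `SF` (supporting-read fraction,
#' 3 decimals).
#'
#' @param calls call data.frame from [callSnvs()].
#' @param genome the [ReferenceGenome-class].
#' @param path output file.
#' @param sampleId label written in the header.
#' @return The path, invisibly.
#' @export
writeCallsVcf <- function(calls, genome, path, sampleId = "strain") {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", refId(genome), ",length=", genomeLength(genome), ">"),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Aligned read depth\">",
    "##INFO=<ID=SF,Number=1,Type=Float,Description=\"Supporting read fraction\">",
    paste0("##sample=", sampleId),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(calls) > 0) {
    ord <- order(calls$position)
    calls <- calls[ord, , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;SF=%.3f",
                    refId(genome), calls$position, calls$ref, calls$alt,
                    calls$depth, calls$support_fraction)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the merged multi-strain classification as VCF 4.2
#'
#' One record per variant key with INFO fields `NS` (number of carrier
#' strains), `CLASS` (`parental`/`unique`/`shared_subset`) and `STRAINS`.
#'
#' @param classified data.frame from [classifyVariants()].
#' @param genome the [ReferenceGenome-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeMergedVcf <- function(classified, genome, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", refId(genome), ",length=", genomeLength(genome), ">"),
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Carrier strain count\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"parental, unique or shared_subset\">",
    "##INFO=<ID=STRAINS,Number=.,Type=String,Description=\"Carrier strains\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(classified) > 0) {
    cl <- classified[order(classified$position), , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tNS=%d;CLASS=%s;STRAINS=%s",
                    refId(genome), cl$position, cl$ref, cl$alt,
                    cl$n_strains_present, cl$class,
                    gsub(",", "|", cl$carrier_strains))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write alignments as SAM
#'
#' Minimal single-reference SAM: aligned reads carry FLAG 0/16 (strand), a
#' full-length match CIGAR and an `NM` tag with the mismatch count; orphan
#' reads are emitted unmapped (FLAG 4); suppressed reads are emitted
#' unmapped with an additional `ZS:Z:suppressed` tag.
#'
#' @param alignments alignment data.frame from [alignReadSet()].
#' @param reads the read set (`DNAStringSet` or character, aligner order).
#' @param genome the [ReferenceGenome-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeSam <- function(alignments, reads, genome, path) {
  seqs <- as.character(reads)
  rl <- nchar(seqs)
  qual <- vapply(rl, function(n) strrep("I", n), character(1))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", refId(genome), "\tLN:", genomeLength(genome)),
              "@PG\tID:suppressorSeq\tPN:suppressorSeq")
  aligned <- alignments$status == "aligned"
  flag <- ifelse(aligned, ifelse(alignments$strand == "-", 16L, 0L), 4L)
  outSeq <- seqs
  outSeq[aligned & alignments$strand == "-"] <-
    revComp(seqs[aligned & alignments$strand == "-"])
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 alignments$read_id, flag,
                 ifelse(aligned, refId(genome), "*"),
                 ifelse(aligned, alignments$position, 0L),
                 ifelse(aligned, 255L, 0L),
                 ifelse(aligned, paste0(rl, "M"), "*"),
                 outSeq, qual)
  rec[aligned] <- paste0(rec[aligned], "\tNM:i:", alignments$mismatches[aligned])
  supp <- alignments$status == "suppressed"
  rec[supp] <- paste0(rec[supp], "\tZS:Z:suppressed")
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Dump a pileup as TSV
#'
#' Columns `position`, `depth`, `nA`, `nC`, `nG`, `nT`.
#'
#' @param pileup matrix from [buildPileup()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writePileupTsv <- function(pileup, path) {
  utils::write.table(pileupTable(pileup), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read alignments back from a SAM file
#'
#' Minimal parser for the single-reference SAM written by [writeSam()];
#' returns the alignment triage table consumed by [buildPileup()] together
#' with the read sequences in sequencing orientation.
#'
#' @param path SAM file.
#' @return A list with `alignments` (data.frame `read_id`, `status`,
#'   `position`, `strand`, `mismatches`) and `reads` (named character
#'   vector, as-sequenced orientation).
#' @export
readSamAlignments <- function(path) {
  lines <- readLines(path)
  rec <- lines[!startsWith(lines, "@")]
  f <- strsplit(rec, "\t", fixed = TRUE)
  readId <- vapply(f, `[[`, character(1), 1L)
  flag <- as.integer(vapply(f, `[[`, character(1), 2L))
  pos <- as.integer(vapply(f, `[[`, character(1), 4L))
  seqs <- vapply(f, `[[`, character(1), 10L)
  tags <- vapply(f, function(x) paste(x[-(1:11)], collapse = "\t"), character(1))
  suppressed <- grepl("ZS:Z:suppressed", tags, fixed = TRUE)
  unmapped <- bitwAnd(flag, 4L) == 4L
  minus <- bitwAnd(flag, 16L) == 16L
  status <- ifelse(suppressed, "suppressed", ifelse(unmapped, "orphan", "aligned"))
  nm <- suppressWarnings(as.integer(sub(".*NM:i:(\\d+).*", "\\1", tags)))
  # SAM stores reverse-strand sequences in reference orientation; undo that
  seqs[status == "aligned" & minus] <- revComp(seqs[status == "aligned" & minus])
  aln <- data.frame(read_id = readId, status = status,
                    position = ifelse(status == "aligned", pos, NA_integer_),
                    strand = ifelse(status == "aligned",
                                    ifelse(minus, "-", "+"), NA_character_),
                    mismatches = ifelse(status == "aligned", nm, NA_integer_),
                    stringsAsFactors = FALSE)
  list(alignments = aln, reads = stats::setNames(seqs, readId))
}

#' Read single-strain SNV calls back from VCF
#'
#' Minimal parser for the VCF written by [writeCallsVcf()].
#'
#' @param path VCF file.
#' @param strainId strain label stamped on the calls (default: the
#'   `##sample=` header entry, if present).
#' @return A call data.frame as produced by [callSnvs()].
#' @export
readCallsVcf <- function(path, strainId = NULL) {
  lines <- readLines(path)
  if (is.null(strainId)) {
    s <- grep("^##sample=", lines, value = TRUE)
    strainId <- if (length(s)) sub("^##sample=", "", s[1]) else "strain"
  }
  rec <- lines[!startsWith(lines, "#")]
  if (length(rec) == 0)
    return(data.frame(strain = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      support_fraction = numeric(0), depth = integer(0)))
  f <- strsplit(rec, "\t", fixed = TRUE)
  info <- vapply(f, `[[`, character(1), 8L)
  data.frame(strain = strainId,
             position = as.integer(vapply(f, `[[`, character(1), 2L)),
             ref = vapply(f, `[[`, character(1), 4L),
             alt = vapply(f, `[[`, character(1), 5L),
             support_fraction = as.numeric(sub(".*SF=([0-9.]+).*", "\\1", info)),
             depth = as.integer(sub(".*DP=(\\d+).*", "\\1", info)),
             stringsAsFactors = FALSE)
}
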