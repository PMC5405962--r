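## End-to-end orchestration: simulate -> align -> call -> classify ->
## annotate, with optional on-disk artifacts and a run report.

#' The standard 13-strain simulation scenario
#'
#' A 50-kb toy genome with 20 CDS and one tRNA; 17 shared (parental) SNVs
#' whose effect mix echoes a typical lab-parent divergence set (three
#' intergenic, one synonymous, two premature stops, one tRNA anticodon
#' CGA to CTA, ten missense); and one private variant per strain: eleven
#' SNVs (two of them amber stop gains in essential genes, two intergenic,
#' seven missense) plus two strains carrying a 3-bp deletion, which the
#' SNV-only caller cannot see. Reads are 36 nt single-end at 30X with a
#' 0.3% per-base substitution-error rate.
#'
#' @param seed master integer seed.
#' @return A [PipelineConfig-class].
#' @export
standardScenario <- function(seed = 0) {
  shared <- c("anticodon", "synonymous", "stop_gain", "stop_gain",
              rep("missense", 10), rep("intergenic", 3))
  unique <- data.frame(
    strain = sprintf("SUP%02d", 1:13),
    kind = c("SNV", "SNV", "DEL", "SNV", "SNV", "SNV", "SNV", "SNV", "SNV",
             "SNV", "SNV", "DEL", "SNV"),
    effect = c("intergenic", "stop_gain_amber", "intergenic", "intergenic",
               "missense", "missense", "missense", "missense", "missense",
               "missense", "stop_gain_amber", "intergenic", "missense"),
    essential = c(NA, TRUE, NA, NA, NA, NA, NA, NA, NA, NA, TRUE, NA, NA),
    stringsAsFactors = FALSE)
  PipelineConfig(genomeLength = 50000, geneCount = 20, trnaCount = 1,
                 nStrains = 13, sharedSpec = shared, uniqueSpec = unique,
                 readLength = 36, meanDepth = 30, errorRate = 0.003,
                 seed = seed)
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full resequencing pipeline
#'
#' Generates the annotated toy reference, implants shared and strain-private
#' variants, simulates error-bearing reads per strain, aligns them under the
#' two-mismatch acceptance rule with multi-map suppression, calls SNVs by
#' strict read consensus, classifies variants across strains as parental /
#' unique / shared-subset, and annotates protein-level effects including
#' amber-suppressor readthrough. Identical config and seed give identical
#' results (and identical artifact bytes when `outdir` is set).
#'
#' @param config a [PipelineConfig-class], e.g. [standardScenario()].
#' @param outdir optional directory for on-disk artifacts (FASTA, GFF3,
#'   per-strain FASTQ and VCF, statistics and variant TSVs, merged VCF).
#' @param writeSam also write per-strain SAM files (large; off by default).
#' @param verbose log per-stage progress and counts.
#' @return An object of class `suppressorRun`: a list with elements
#'   `config`, `genome`, `features`, `truth`, `stats` (per-strain
#'   [AlignmentStats-class]), `callSets`, `matrix`
#'   ([VariantMatrix-class]), `classified`, `annotated`, `contexts`,
#'   `summary` (class counts, per-strain unique counts, recovery vs truth)
#'   and `minSupport` (minimum supporting-read fraction over all calls).
#' @export
runPipeline <- function(config, outdir = NULL, writeSam = FALSE,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message("[suppressorSeq] ", ...)
  t0 <- Sys.time()
  stamp <- function(stage) if (verbose)
    message(sprintf("[suppressorSeq] %-9s done at %+.1fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))

  ref <- withStage("simulate", generateReference(config))
  imp <- withStage("simulate", implantVariants(
    ref$genome, ref$features, config@sharedSpec, config@uniqueSpec,
    seed = config@seed + config@nStrains + 1L,
    readLength = config@readLength, delLength = config@delLength))
  say(genomeLength(ref$genome), " bp reference, ",
      length(ref$features), " features, ", nrow(imp$truth),
      " implanted variants")
  stamp("simulate")

  index <- withStage("align", buildIndex(ref$genome, k = config@seedLength,
                                         readLength = config@readLength))
  strains <- config@uniqueSpec$strain
  statsList <- list()
  callSets <- list()
  for (i in seq_along(strains)) {
    s <- strains[i]
    reads <- withStage("simulate", simulateReads(
      imp$strainGenomes[[s]], config, strainId = s, seed = config@seed + i))
    aln <- withStage("align", alignReadSet(reads, index, ref$genome,
                                           maxMismatch = config@maxMismatch,
                                           strainId = s))
    pile <- withStage("call", buildPileup(aln$alignments, reads, ref$genome))
    calls <- withStage("call", callSnvs(pile, ref$genome,
                                        minFraction = config@minFraction,
                                        minDepth = config@minDepth,
                                        strainId = s))
    statsList[[s]] <- aln$stats
    callSets[[s]] <- calls
    say(s, ": ", aln$stats@totalReads, " reads, ",
        aln$stats@alignedReads, " aligned, ", nrow(calls), " calls")
    if (!is.null(outdir)) {
      dir.create(file.path(outdir, "reads"), recursive = TRUE, showWarnings = FALSE)
      dir.create(file.path(outdir, "vcf"), recursive = TRUE, showWarnings = FALSE)
      writeReadsFastq(reads, file.path(outdir, "reads", paste0(s, ".fastq")))
      writeCallsVcf(calls, ref$genome, file.path(outdir, "vcf", paste0(s, ".vcf")),
                    sampleId = s)
      if (writeSam) {
        dir.create(file.path(outdir, "sam"), recursive = TRUE, showWarnings = FALSE)
        writeSam(aln$alignments, reads, ref$genome,
                 file.path(outdir, "sam", paste0(s, ".sam")))
      }
    }
  }
  stamp("align")

  vm <- withStage("classify", buildVariantMatrix(callSets))
  classified <- withStage("classify", classifyVariants(vm))
  say(nrow(classified), " distinct variant keys: ",
      sum(classified$class == "parental"), " parental, ",
      sum(classified$class == "unique"), " unique, ",
      sum(classified$class == "shared_subset"), " shared_subset")
  stamp("classify")

  anno <- withStage("annotate",
                    annotateVariants(classified, ref$features, ref$genome))
  contexts <- withStage("annotate", lapply(callSets, function(cs)
    strainContext(cs, ref$features, ref$genome)))
  # a variant's readthrough is judged in its carrier strains; with the
  # anticodon variant parental, carrier contexts agree across strains
  suppressorStrains <- names(contexts)[vapply(contexts, `[[`, logical(1),
                                              "amber_suppressor")]
  anno$readthrough_applied <- logical(nrow(anno))
  for (r in seq_len(nrow(anno))) {
    carriers <- strsplit(classified$carrier_strains[r], ",")[[1]]
    if (length(carriers) > 0 && all(carriers %in% suppressorStrains)) {
      ctx <- list(amber_suppressor = TRUE)
      anno[r, ] <- applyReadthrough(anno[r, , drop = FALSE], ctx, ref$features)
    }
  }
  annotated <- cbind(classified[, c("position", "ref", "alt",
                                    "n_strains_present", "class",
                                    "carrier_strains")],
                     anno[, c("context", "gene", "codon_number",
                              "effect_class", "notation",
                              "readthrough_applied")])
  stamp("annotate")

  summary <- summarizeVariants(classified, strains, truth = imp$truth)
  allSupport <- unlist(lapply(callSets, function(cs) cs$support_fraction))
  minSupport <- if (length(allSupport)) min(allSupport) else NA_real_

  run <- structure(list(config = config, genome = ref$genome,
                        features = ref$features, truth = imp$truth,
                        stats = statsList, callSets = callSets, matrix = vm,
                        classified = classified, annotated = annotated,
                        contexts = contexts, summary = summary,
                        minSupport = minSupport),
                   class = "suppressorRun")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeReferenceFasta(ref$genome, file.path(outdir, "reference.fasta"))
    writeFeaturesGff3(ref$features, file.path(outdir, "features.gff3"))
    writeTruthTsv(imp$truth, file.path(outdir, "truth.tsv"))
    writeStatsTsv(statsList, file.path(outdir, "alignment_stats.tsv"))
    writeMergedVcf(classified, ref$genome, file.path(outdir, "merged.vcf"))
    tb <- tables34(run)
    utils::write.table(tb$parental, file.path(outdir, "parental_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tb$unique, file.path(outdir, "unique_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  run
}

#' @export
print.suppressorRun <- function(x, ...) {
  cat("suppressorSeq run:", x$config@nStrains, "strains on a",
      genomeLength(x$genome), "bp reference\n")
  cat("  class counts: ",
      paste(names(x$summary$class_counts), x$summary$class_counts,
            sep = " = ", collapse = ", "), "\n", sep = "")
  ups <- x$summary$unique_per_strain
  cat("  strains with one unique call:", sum(ups == 1),
      "| with none:", sum(ups == 0), "\n")
  if (!is.na(x$minSupport))
    cat(sprintf("  minimum supporting-read fraction over all calls: %.4f\n",
                x$minSupport))
  invisible(x)
}

#' Render the per-strain read-statistics table
#'
#' @param statsList list of [AlignmentStats-class] (or a `suppressorRun`).
#' @return data.frame with counts, percentage strings (2 decimals, trailing
#'   `%`) and approximate depth (`<n>X`) per strain.
#' @export
renderStatsTable <- function(statsList) {
  if (inherits(statsList, "suppressorRun")) statsList <- statsList$stats
  do.call(rbind, lapply(statsList, function(st) {
    df <- as.data.frame(st)
    data.frame(strain = df$strain, total_reads = df$total_reads,
               aligned_reads = df$aligned_reads,
               aligned_pct = sprintf("%.2f%%", df$aligned_pct),
               suppressed_reads = df$suppressed_reads,
               suppressed_pct = sprintf("%.2f%%", df$suppressed_pct),
               orphan_reads = df$orphan_reads,
               orphan_pct = sprintf("%.2f%%", df$orphan_pct),
               depth = paste0(df$depth, "X"), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
}

#' Read-statistics table of a run
#'
#' @param run a `suppressorRun` from [runPipeline()].
#' @return The formatted per-strain statistics data.frame.
#' @export
statsTable <- function(run) renderStatsTable(run$stats)

#' Parental and unique variant tables of a run
#'
#' Mirrors the two variant tables of a suppressor-hunt report: shared
#' (parental) variants with carrier count, and per-strain unique variants.
#' The `effect` column carries the protein-mutation notation (`-` for
#' intergenic sites).
#'
#' @param run a `suppressorRun` from [runPipeline()].
#' @return A list with data.frames `parental` (`position ref alt gene effect
#'   n_strains`) and `unique` (`strain position ref alt gene effect`).
#' @export
tables34 <- function(run) {
  ann <- run$annotated
  par <- ann[ann$class == "parental", , drop = FALSE]
  parental <- data.frame(position = par$position, ref = par$ref,
                         alt = par$alt, gene = par$gene,
                         effect = par$notation,
                         n_strains = par$n_strains_present,
                         stringsAsFactors = FALSE, row.names = NULL)
  uni <- ann[ann$class == "unique", , drop = FALSE]
  unique <- data.frame(strain = uni$carrier_strains, position = uni$position,
                       ref = uni$ref, alt = uni$alt, gene = uni$gene,
                       effect = uni$notation, stringsAsFactors = FALSE,
                       row.names = NULL)
  unique <- unique[order(unique$strain), , drop = FALSE]
  rownames(unique) <- NULL
  list(parental = parental[order(parental$position), , drop = FALSE],
       unique = unique)
}
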