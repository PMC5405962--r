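## Cross-strain combination of call sets and parental/unique classification.

#' Build the variant-by-strain incidence matrix
#'
#' Takes the union of `(position, ref, alt)` keys over all strains' call
#' sets and records which strains carry each key. Two strains reporting
#' different reference alleles at the same position indicate an upstream
#' inconsistency (simulator or caller bug) and raise an error.
#'
#' @param callSets named list of per-strain call data.frames from
#'   [callSnvs()]; at least two strains.
#' @return A [VariantMatrix-class].
#' @export
buildVariantMatrix <- function(callSets) {
  if (length(callSets) < 2)
    stop("at least two strains are required for cross-strain comparison")
  strains <- names(callSets)
  if (is.null(strains) || any(!nzchar(strains)))
    stop("callSets must be a named list (strain ids)")
  all <- do.call(rbind, lapply(strains, function(s) {
    cs <- callSets[[s]]
    if (nrow(cs) == 0)
      return(data.frame(strain = character(0), position = integer(0),
                        ref = character(0), alt = character(0)))
    data.frame(strain = s, position = cs$position, ref = cs$ref, alt = cs$alt,
               stringsAsFactors = FALSE)
  }))
  if (nrow(all) > 0) {
    refByPos <- unique(all[, c("position", "ref")])
    if (anyDuplicated(refByPos$position))
      stop("consistency error: strains disagree on the reference allele at ",
           "position(s) ",
           paste(refByPos$position[duplicated(refByPos$position)], collapse = ", "))
  }
  keys <- unique(all[, c("position", "ref", "alt")])
  keys <- keys[order(keys$position, keys$alt), , drop = FALSE]
  rownames(keys) <- NULL
  presence <- matrix(FALSE, nrow = nrow(keys), ncol = length(strains))
  if (nrow(keys) > 0) {
    keyId <- paste(keys$position, keys$ref, keys$alt)
    for (j in seq_along(strains)) {
      cs <- all[all$strain == strains[j], , drop = FALSE]
      presence[, j] <- keyId %in% paste(cs$position, cs$ref, cs$alt)
    }
  }
  methods::new("VariantMatrix", keys = keys, strains = strains,
               presence = presence)
}

#' Classify variants as parental, unique or shared-subset
#'
#' A variant present in every strain is `parental` (a difference between the
#' common lab parent and the public reference); a variant present in exactly
#' one strain is `unique` (the suppressor candidate of that strain).
#' Anything in between is `shared_subset`, which the single-mutation model
#' does not predict; such keys are flagged for manual review via a message.
#'
#' @param matrix a [VariantMatrix-class].
#' @return data.frame with columns `position`, `ref`, `alt`,
#'   `n_strains_present`, `class`, `carrier_strains` (comma-separated).
#' @export
classifyVariants <- function(matrix) {
  keys <- variantKeys(matrix)
  pres <- presenceMatrix(matrix)
  n <- rowSums(pres)
  total <- length(strainIds(matrix))
  cls <- ifelse(n == total, "parental",
                ifelse(n == 1, "unique", "shared_subset"))
  carriers <- apply(pres, 1, function(row)
    paste(strainIds(matrix)[row], collapse = ","))
  if (nrow(keys) == 0) carriers <- character(0)
  out <- data.frame(keys, n_strains_present = as.integer(n), class = cls,
                    carrier_strains = carriers, stringsAsFactors = FALSE)
  nAnom <- sum(out$class == "shared_subset")
  if (nAnom > 0)
    message(nAnom, " variant(s) present in a strict subset of strains ",
            "(shared_subset): flagged for manual review")
  out
}

#' Summarize classified variants, optionally against the simulation truth
#'
#' @param classified data.frame from [classifyVariants()].
#' @param strains character vector of all strain ids (so strains with zero
#'   unique calls are reported).
#' @param truth optional truth data.frame from [implantVariants()]; when
#'   supplied, per-class sensitivity and precision of the SNV calls are
#'   reported (deletions in the truth set are, by design, invisible to the
#'   SNV caller and excluded from the denominator).
#' @return A list with `class_counts`, `unique_per_strain` (named integer),
#'   and, when truth is given, `recovery` (data.frame with per-class
#'   sensitivity/precision).
#' @export
summarizeVariants <- function(classified, strains, truth = NULL) {
  classCounts <- c(parental = sum(classified$class == "parental"),
                   unique = sum(classified$class == "unique"),
                   shared_subset = sum(classified$class == "shared_subset"))
  uniquePerStrain <- stats::setNames(integer(length(strains)), strains)
  uni <- classified[classified$class == "unique", , drop = FALSE]
  if (nrow(uni) > 0) {
    tab <- table(uni$carrier_strains)
    uniquePerStrain[names(tab)] <- as.integer(tab)
  }
  out <- list(class_counts = classCounts, unique_per_strain = uniquePerStrain)
  if (!is.null(truth)) {
    snvTruth <- truth[truth$kind == "SNV", , drop = FALSE]
    recov <- do.call(rbind, lapply(c("parental", "unique"), function(cl) {
      tKeys <- with(snvTruth[snvTruth$class == cl, , drop = FALSE],
                    paste(position, ref, alt))
      cKeys <- with(classified[classified$class == cl, , drop = FALSE],
                    paste(position, ref, alt))
      data.frame(class = cl, n_truth = length(tKeys), n_called = length(cKeys),
                 sensitivity = if (length(tKeys)) mean(tKeys %in% cKeys) else NA,
                 precision = if (length(cKeys)) mean(cKeys %in% tKeys) else NA)
    }))
    out$recovery <- recov
  }
  out
}
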