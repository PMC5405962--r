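# hand-built micro-genomes with a single feature give full control over
# codon content
mkCdsGenome <- function(internalCodons, strand = "+", essential = FALSE,
                        pad = 40) {
  cds <- paste0("ATG", paste(internalCodons, collapse = ""), "TAA")
  insert <- if (strand == "+") cds else oracleRevComp(cds)
  g <- paste0(strrep("T", pad), insert, strrep("T", pad))
  genome <- ReferenceGenome(g, id = "micro")
  features <- GenomicRanges::GRanges(
    "micro", IRanges::IRanges(pad + 1, pad + nchar(cds)), strand = strand,
    feature_id = "cds_01", kind = "CDS", gene_name = "geneX",
    product = "hypothetical protein", essential = essential,
    anticodon_offset = NA_integer_)
  list(genome = genome, features = features, cdsStart = pad + 1,
       cdsEnd = pad + nchar(cds))
}

mkTrnaGenome <- function(anticodon = "CGA", offset = 10L, len = 76L, pad = 30) {
  body <- strrep("A", len)
  body <- paste0(substr(body, 1, offset), anticodon,
                 substr(body, offset + 4, len))
  g <- paste0(strrep("C", pad), body, strrep("C", pad))
  genome <- ReferenceGenome(g, id = "micro")
  features <- GenomicRanges::GRanges(
    "micro", IRanges::IRanges(pad + 1, pad + len), strand = "+",
    feature_id = "trna_01", kind = "tRNA", gene_name = "serX1",
    product = "tRNA-Ser", essential = FALSE, anticodon_offset = offset)
  list(genome = genome, features = features, acStart = pad + 1 + offset)
}

test_that("positions localize to CDS, tRNA or intergenic", {
  fx <- mkCdsGenome(rep("GCT", 10))
  expect_equal(locateFeature(fx$cdsStart + 5, fx$features, fx$genome)$context,
               "CDS")
  expect_equal(locateFeature(5, fx$features, fx$genome)$context, "intergenic")
  tx <- mkTrnaGenome()
  expect_equal(locateFeature(tx$acStart, tx$features, tx$genome)$context,
               "tRNA")
  expect_error(locateFeature(10^6, fx$features, fx$genome), "bounds")
  # overlapping features are an annotation-model error
  twice <- c(fx$features, fx$features)
  expect_error(locateFeature(fx$cdsStart + 5, twice, fx$genome),
               "annotation-model")
})

test_that("codon effects cover missense, synonymous and stop subtypes", {
  # residue 5 = TGG (Trp); G->A at its 2nd base creates the TAG amber stop
  internal <- rep("GCT", 10); internal[4] <- "TGG"  # residue 5 overall
  fx <- mkCdsGenome(internal)
  pos <- fx$cdsStart + 3 * 4 + 1   # 2nd base of codon 5
  eff <- codonEffect(pos, "G", "A", fx$features, fx$genome)
  expect_equal(eff$effect_class, "stop_gain_amber")
  expect_equal(eff$notation, "W5Stop")  # non-essential gene: plain Stop

  # the same change in an essential gene is written as Amber
  fxE <- mkCdsGenome(internal, essential = TRUE)
  effE <- codonEffect(pos, "G", "A", fxE$features, fxE$genome)
  expect_equal(effE$notation, "W5Amber")
  expect_false(effE$readthrough_applied)

  # TGG -> TGA at the 3rd base is an opal stop
  effOpal <- codonEffect(pos + 1, "G", "A", fx$features, fx$genome)
  expect_equal(effOpal$effect_class, "stop_gain_opal")

  # synonymous GAA -> GAG at residue 38 is written E38E
  internal38 <- rep("GCT", 40); internal38[37] <- "GAA"
  fx38 <- mkCdsGenome(internal38)
  pos38 <- fx38$cdsStart + 3 * 37 + 2   # 3rd base of codon 38
  eff38 <- codonEffect(pos38, "A", "G", fx38$features, fx38$genome)
  expect_equal(eff38$effect_class, "synonymous")
  expect_equal(eff38$notation, "E38E")

  # missense CAG -> CTG (Gln -> Leu)
  internalM <- rep("GCT", 10); internalM[2] <- "CAG"  # residue 3
  fxM <- mkCdsGenome(internalM)
  posM <- fxM$cdsStart + 3 * 2 + 1
  effM <- codonEffect(posM, "A", "T", fxM$features, fxM$genome)
  expect_equal(effM$effect_class, "missense")
  expect_equal(effM$notation, "Q3L")

  # reference-allele mismatch is a consistency error
  expect_error(codonEffect(posM, "C", "T", fxM$features, fxM$genome),
               "consistency error")
})

test_that("annotation is symmetric under strand reversal", {
  internal <- rep("GCT", 12); internal[6] <- "CAG"  # residue 7, Gln
  plus <- mkCdsGenome(internal, strand = "+")
  minus <- mkCdsGenome(internal, strand = "-")
  # 2nd base of codon 7 on the coding strand
  offsetInCds <- 3 * 6 + 2
  posPlus <- plus$cdsStart + offsetInCds - 1
  posMinus <- minus$cdsEnd - offsetInCds + 1
  effPlus <- codonEffect(posPlus, "A", "T", plus$features, plus$genome)
  effMinus <- codonEffect(posMinus, "T", "A", minus$features, minus$genome)
  expect_equal(effPlus$notation, effMinus$notation)   # Q7L both ways
  expect_equal(effPlus$effect_class, effMinus$effect_class)
  expect_equal(effMinus$notation, "Q7L")
})

test_that("anticodon variants flag amber suppression only for CGA->CTA", {
  tx <- mkTrnaGenome("CGA")
  mid <- tx$acStart + 1
  eff <- anticodonEffect(mid, "G", "T", tx$features, tx$genome)
  expect_equal(eff$effect_class, "anticodon_change")
  expect_true(eff$amber_suppressor)
  expect_equal(eff$notation, "CGA>CTA")

  # CGA -> CAA does not pair the TAG stop: changed but not a suppressor
  effCaa <- anticodonEffect(mid, "G", "A", tx$features, tx$genome)
  expect_equal(effCaa$effect_class, "anticodon_change")
  expect_false(effCaa$amber_suppressor)

  # a body variant outside the anticodon is anticodon-neutral
  effBody <- anticodonEffect(tx$acStart + 10, "A", "G", tx$features, tx$genome)
  expect_equal(effBody$effect_class, "trna_body")
  expect_false(effBody$amber_suppressor)
})

test_that("readthrough gating requires suppressor strain + amber + essential", {
  internal <- rep("GCT", 10); internal[4] <- "CAG"
  fxE <- mkCdsGenome(internal, essential = TRUE)
  pos <- fxE$cdsStart + 3 * 4 + 1
  amber <- codonEffect(pos, "A", "T", fxE$features, fxE$genome)  # CAG->CTG? no:
  # CAG 2nd base A->T gives CTG (missense); use 1st base C->T for TAG
  amber <- codonEffect(pos - 1, "C", "T", fxE$features, fxE$genome)
  expect_equal(amber$effect_class, "stop_gain_amber")
  expect_equal(amber$notation, "Q5Amber")

  supp <- list(strain_id = "s", amber_suppressor = TRUE)
  noSupp <- list(strain_id = "s", amber_suppressor = FALSE)
  withS <- applyReadthrough(amber, supp, fxE$features)
  expect_equal(withS$notation, "Q5Amber(S)")
  expect_true(withS$readthrough_applied)
  without <- applyReadthrough(amber, noSupp, fxE$features)
  expect_equal(without$notation, "Q5Amber")
  expect_false(without$readthrough_applied)

  # opal stop gains are never modified, even in a suppressor strain
  internalW <- rep("GCT", 10); internalW[4] <- "TGG"
  fxW <- mkCdsGenome(internalW, essential = TRUE)
  opal <- codonEffect(fxW$cdsStart + 3 * 4 + 2, "G", "A", fxW$features,
                      fxW$genome)
  expect_equal(opal$effect_class, "stop_gain_opal")
  opalAfter <- applyReadthrough(opal, supp, fxW$features)
  expect_equal(opalAfter$notation, opal$notation)
  expect_false(opalAfter$readthrough_applied)

  # amber stop gain in a NON-essential gene: no readthrough suffix
  fxN <- mkCdsGenome(internal, essential = FALSE)
  amberN <- codonEffect(pos - 1, "C", "T", fxN$features, fxN$genome)
  expect_equal(amberN$notation, "Q5Stop")
  afterN <- applyReadthrough(amberN, supp, fxN$features)
  expect_false(afterN$readthrough_applied)
})

test_that("strain context derives amber-suppressor status from the calls", {
  tx <- mkTrnaGenome("CGA")
  mid <- tx$acStart + 1
  calls <- data.frame(strain = "s1", position = mid, ref = "G", alt = "T",
                      stringsAsFactors = FALSE)
  expect_true(strainContext(calls, tx$features, tx$genome)$amber_suppressor)
  callsOther <- data.frame(strain = "s1", position = mid, ref = "G", alt = "A",
                           stringsAsFactors = FALSE)
  expect_false(strainContext(callsOther, tx$features,
                             tx$genome)$amber_suppressor)
  expect_false(strainContext(calls[0, ], tx$features,
                             tx$genome)$amber_suppressor)
})
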