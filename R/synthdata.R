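## Synthetic-data module: toy reference genomes, variant implantation and
## short-read simulation. Everything is deterministic given the seed(s).

CDS_MIN_CODONS <- 100L
CDS_MAX_CODONS <- 300L
TRNA_LENGTH <- 76L
TRNA_ANTICODON_OFFSET <- 32L  # 0-based offset of the anticodon triplet
MIN_INTERGENIC_GAP <- 120L

#' Generate a toy annotated reference genome
#'
#' Builds a random A/C/G/T chromosome carrying non-overlapping CDS and tRNA
#' features separated by intergenic gaps. Every CDS is a valid ORF on its
#' coding strand (starts with ATG, ends with a stop codon, no internal stop).
#' Exactly one tRNA carries the anticodon CGA (the serine-tRNA analogue whose
#' single-base anticodon mutation CGA->CTA converts the strain into an amber
#' suppressor). A subset of CDS features is flagged essential.
#'
#' @param config a [SimulationConfig-class].
#' @return A list with elements `genome` ([ReferenceGenome-class]) and
#'   `features` (a [GenomicRanges::GRanges] with metadata columns
#'   `feature_id`, `kind`, `gene_name`, `product`, `essential`,
#'   `anticodon_offset`).
#' @export
#' @examples
#' cfg <- SimulationConfig(genomeLength = 20000, geneCount = 5, trnaCount = 1,
#'                         seed = 1)
#' ref <- generateReference(cfg)
#' genomeLength(ref$genome)
generateReference <- function(config) {
  stopifnot(methods::is(config, "SimulationConfig"))
  set.seed(config@seed)
  L <- config@genomeLength
  nCds <- config@geneCount
  nTrna <- config@trnaCount
  if (nTrna < 1L)
    stop("at least one tRNA feature is required (the amber-suppressor locus)")

  codons <- sample(seq(CDS_MIN_CODONS, CDS_MAX_CODONS), nCds, replace = TRUE)
  cdsLen <- codons * 3L
  featLen <- c(cdsLen, rep(TRNA_LENGTH, nTrna))
  nFeat <- length(featLen)
  slack <- L - sum(featLen) - (nFeat + 1L) * MIN_INTERGENIC_GAP
  if (slack < 0)
    stop("sizing error: requested features do not fit in genome length ",
         L, " (need at least ", sum(featLen) + (nFeat + 1L) * MIN_INTERGENIC_GAP,
         " bases)")

  kind <- sample(c(rep("CDS", nCds), rep("tRNA", nTrna)))
  extra <- as.vector(stats::rmultinom(1, slack, rep(1, nFeat + 1L)))
  gaps <- MIN_INTERGENIC_GAP + extra

  sequence <- randomDna(L)
  start <- integer(nFeat); end <- integer(nFeat)
  strand <- character(nFeat)
  cdsSeen <- 0L; trnaSeen <- 0L
  lens <- integer(nFeat)
  lens[kind == "CDS"] <- cdsLen
  lens[kind == "tRNA"] <- TRNA_LENGTH
  anticodons <- character(nFeat)
  pos <- gaps[1L] + 1L
  for (i in seq_len(nFeat)) {
    start[i] <- pos
    end[i] <- pos + lens[i] - 1L
    if (kind[i] == "CDS") {
      cdsSeen <- cdsSeen + 1L
      strand[i] <- sample(c("+", "-"), 1L)
      orf <- randomOrf(lens[i] %/% 3L)
      insert <- if (strand[i] == "+") orf else revComp(orf)
    } else {
      trnaSeen <- trnaSeen + 1L
      strand[i] <- "+"  # anticodon stored in forward orientation
      anticodons[i] <- if (trnaSeen == 1L) "CGA" else
        paste(sample(BASES, 3L, replace = TRUE), collapse = "")
      if (trnaSeen > 1L && anticodons[i] == "CGA") anticodons[i] <- "CGT"
      body <- randomDna(TRNA_LENGTH)
      insert <- replaceAt(body, TRNA_ANTICODON_OFFSET + 1L, anticodons[i])
    }
    sequence <- replaceAt(sequence, start[i], insert)
    pos <- end[i] + gaps[i + 1L] + 1L
  }

  cdsIdx <- which(kind == "CDS")
  nEss <- min(nCds, max(2L, round(0.4 * nCds)))
  essential <- logical(nFeat)
  essential[sample(cdsIdx, nEss)] <- TRUE

  featureId <- character(nFeat)
  geneName <- character(nFeat)
  product <- character(nFeat)
  featureId[cdsIdx] <- sprintf("cds_%02d", seq_along(cdsIdx))
  geneName[cdsIdx] <- sprintf("gene%02d", seq_along(cdsIdx))
  product[cdsIdx] <- "hypothetical protein"
  trnaIdx <- which(kind == "tRNA")
  featureId[trnaIdx] <- sprintf("trna_%02d", seq_along(trnaIdx))
  geneName[trnaIdx] <- sprintf("serX%d", seq_along(trnaIdx))
  product[trnaIdx] <- paste0("tRNA-Ser (anticodon ", anticodons[trnaIdx], ")")

  genome <- ReferenceGenome(sequence, id = "toy_ref")
  features <- GenomicRanges::GRanges(
    seqnames = refId(genome),
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand,
    feature_id = featureId, kind = kind, gene_name = geneName,
    product = product, essential = essential,
    anticodon_offset = ifelse(kind == "tRNA", TRNA_ANTICODON_OFFSET, NA_integer_)
  )
  validateFeatures(features, genome)
  list(genome = genome, features = features)
}

# ORF of nCodon codons: ATG + internal sense codons + one stop codon
randomOrf <- function(nCodon) {
  sense <- setdiff(mkAllCodons(), c(names(STOP_CODONS)))
  internal <- sample(sense, nCodon - 2L, replace = TRUE)
  paste0("ATG", paste(internal, collapse = ""),
         sample(names(STOP_CODONS), 1L))
}

mkAllCodons <- function() {
  g <- expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

#' Validate a feature table against its genome
#'
#' Checks the structural invariants of the annotation: coordinates inside the
#' genome, features non-overlapping, CDS spans divisible by three forming
#' valid ORFs on the coding strand, and tRNA features carrying an in-bounds
#' anticodon offset.
#'
#' @param features a `GRanges` feature table as produced by
#'   [generateReference()].
#' @param genome the matching [ReferenceGenome-class].
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validateFeatures <- function(features, genome) {
  L <- genomeLength(genome)
  st <- GenomicRanges::start(features)
  en <- GenomicRanges::end(features)
  if (any(st < 1L) || any(en > L) || any(st > en))
    stop("feature coordinates out of genome bounds")
  if (length(features) > 1L) {
    hits <- GenomicRanges::findOverlaps(features, ignore.strand = TRUE,
                                        drop.self = TRUE)
    if (length(hits) > 0) stop("features must be non-overlapping")
  }
  md <- S4Vectors::mcols(features)
  seqChr <- refSequence(genome, as.character = TRUE)
  for (i in which(md$kind == "CDS")) {
    span <- en[i] - st[i] + 1L
    if (span %% 3L != 0L) stop("CDS span not divisible by 3: ", md$feature_id[i])
    cds <- substr(seqChr, st[i], en[i])
    if (as.character(GenomicRanges::strand(features[i])) == "-") cds <- revComp(cds)
    if (substr(cds, 1L, 3L) != "ATG")
      stop("CDS does not begin with ATG: ", md$feature_id[i])
    last <- substr(cds, span - 2L, span)
    if (!last %in% names(STOP_CODONS))
      stop("CDS does not end with a stop codon: ", md$feature_id[i])
  }
  for (i in which(md$kind == "tRNA")) {
    off <- md$anticodon_offset[i]
    if (is.na(off) || off < 0L || st[i] + off + 2L > en[i])
      stop("tRNA feature lacks a valid anticodon_offset: ", md$feature_id[i])
  }
  invisible(TRUE)
}

#' Implant shared and strain-private variants
#'
#' Chooses variant sites realizing the requested effects, builds the truth
#' table, and constructs one mutated genome per strain. Every strain carries
#' all shared (parental) variants; each strain additionally carries exactly
#' its own private variant, either an SNV or a short deletion (which an
#' SNV-only caller is blind to). Implanted sites are kept at least one read
#' length apart so no simulated read spans two variants. Each implanted CDS
#' or tRNA SNV is verified against the annotation module: the constructed
#' substitution provably yields the requested effect.
#'
#' @param genome a [ReferenceGenome-class].
#' @param features feature `GRanges` from [generateReference()].
#' @param sharedSpec character vector of intended effects for shared variants
#'   (among `intergenic`, `synonymous`, `missense`, `stop_gain`,
#'   `stop_gain_amber`, `anticodon`).
#' @param uniqueSpec data.frame with one row per strain: `strain`, `kind`
#'   (`"SNV"`, `"DEL"`, or `"NONE"` for a strain with no private variant),
#'   `effect`, optional `essential` (logical; require the target gene to be
#'   essential / non-essential; `NA` = no constraint).
#' @param seed integer seed for site selection.
#' @param readLength minimum spacing between implanted sites (bases).
#' @param delLength deletion length for `DEL` rows (bases).
#' @return A list with `strainGenomes` (named character vector of mutated
#'   genome sequences) and `truth` (data.frame with columns `strain`,
#'   `position`, `ref`, `alt`, `kind`, `class`, `effect`, `gene`).
#' @export
implantVariants <- function(genome, features, sharedSpec, uniqueSpec,
                            seed = 0, readLength = 36, delLength = 3) {
  set.seed(seed)
  if (!"essential" %in% names(uniqueSpec)) uniqueSpec$essential <- NA
  seqChr <- refSequence(genome, as.character = TRUE)
  L <- nchar(seqChr)
  md <- S4Vectors::mcols(features)

  occupied <- integer(0)  # implanted positions (DELs contribute their span)
  farEnough <- function(p) length(occupied) == 0 ||
    min(abs(occupied - p)) >= readLength

  covered <- logical(L)
  for (i in seq_along(features))
    covered[GenomicRanges::start(features)[i]:GenomicRanges::end(features)[i]] <- TRUE
  intergenicPos <- which(!covered)

  pickIntergenic <- function(width = 1L) {
    ok <- intergenicPos[intergenicPos + width - 1L <= L]
    ok <- ok[vapply(ok, function(p) farEnough(p) && farEnough(p + width - 1L),
                    logical(1))]
    # keep the whole span intergenic
    ok <- ok[vapply(ok, function(p) all(!covered[p:(p + width - 1L)]), logical(1))]
    if (length(ok) == 0) stop("effect-construction error: no intergenic site left")
    ok[sample.int(length(ok), 1L)]
  }

  pickCdsSite <- function(effect, essential = NA) {
    cdsIdx <- which(md$kind == "CDS")
    if (!is.na(essential)) cdsIdx <- cdsIdx[md$essential[cdsIdx] == essential]
    if (length(cdsIdx) == 0)
      stop("effect-construction error: no CDS matches the essentiality constraint")
    for (attempt in seq_len(500L)) {
      fi <- cdsIdx[sample.int(length(cdsIdx), 1L)]
      cand <- cdsSubstitutionCandidates(seqChr, features[fi], effect)
      if (nrow(cand) == 0) next
      cand <- cand[vapply(cand$position, farEnough, logical(1)), , drop = FALSE]
      if (nrow(cand) == 0) next
      row <- cand[sample.int(nrow(cand), 1L), ]
      row$feature <- fi
      return(row)
    }
    stop("effect-construction error: could not realize effect '", effect, "'")
  }

  mkSite <- function(effect, essential = NA) {
    if (effect == "intergenic") {
      p <- pickIntergenic(1L)
      ref <- substr(seqChr, p, p)
      alt <- sample(setdiff(BASES, ref), 1L)
      data.frame(position = p, ref = ref, alt = alt, gene = "-",
                 stringsAsFactors = FALSE)
    } else if (effect == "anticodon") {
      ti <- which(md$kind == "tRNA" &
                  grepl("CGA", md$product))
      if (length(ti) == 0) stop("effect-construction error: no CGA tRNA present")
      ti <- ti[1L]
      p <- GenomicRanges::start(features[ti]) + md$anticodon_offset[ti] + 1L
      if (!farEnough(p))
        stop("effect-construction error: anticodon site conflicts with spacing")
      ref <- substr(seqChr, p, p)
      stopifnot(ref == "G")  # middle base of CGA
      data.frame(position = p, ref = ref, alt = "T", gene = md$gene_name[ti],
                 stringsAsFactors = FALSE)
    } else {
      row <- pickCdsSite(effect, essential)
      data.frame(position = row$position, ref = row$ref, alt = row$alt,
                 gene = md$gene_name[row$feature], stringsAsFactors = FALSE)
    }
  }

  truth <- list()
  # anticodon sites are fixed loci: place them first so the spacing rule
  # cannot be violated by earlier free-position picks
  sharedSpec <- sharedSpec[order(sharedSpec != "anticodon")]
  for (j in seq_along(sharedSpec)) {
    s <- mkSite(sharedSpec[j])
    occupied <- c(occupied, s$position)
    truth[[length(truth) + 1L]] <- data.frame(
      strain = "ALL", position = s$position, ref = s$ref, alt = s$alt,
      kind = "SNV", class = "parental", effect = sharedSpec[j], gene = s$gene,
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(nrow(uniqueSpec))) {
    us <- uniqueSpec[j, ]
    if (us$kind == "NONE") next  # strain carries only the shared variants
    if (us$kind == "DEL") {
      p <- pickIntergenic(delLength)
      occupied <- c(occupied, p, p + delLength - 1L)
      truth[[length(truth) + 1L]] <- data.frame(
        strain = us$strain, position = p,
        ref = substr(seqChr, p, p + delLength - 1L), alt = "-",
        kind = "DEL", class = "unique", effect = us$effect, gene = "-",
        stringsAsFactors = FALSE)
    } else {
      s <- mkSite(us$effect, us$essential)
      occupied <- c(occupied, s$position)
      truth[[length(truth) + 1L]] <- data.frame(
        strain = us$strain, position = s$position, ref = s$ref, alt = s$alt,
        kind = "SNV", class = "unique", effect = us$effect, gene = s$gene,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(strain = character(0), position = integer(0),
               ref = character(0), alt = character(0), kind = character(0),
               class = character(0), effect = character(0),
               gene = character(0), stringsAsFactors = FALSE)

  # cross-check every coding/tRNA SNV against the annotation module
  for (j in seq_len(nrow(truth))) {
    if (truth$kind[j] != "SNV") next
    eff <- annotateVariant(truth$position[j], truth$ref[j], truth$alt[j],
                           features, genome)
    want <- truth$effect[j]
    got <- eff$effect_class
    ok <- switch(want,
      intergenic = got == "intergenic",
      synonymous = got == "synonymous",
      missense = got == "missense",
      stop_gain = got %in% unname(STOP_CODONS),
      stop_gain_amber = got == "stop_gain_amber",
      anticodon = got == "anticodon_change",
      FALSE)
    if (!ok)
      stop("effect-construction error: implanted variant at ", truth$position[j],
           " annotates as '", got, "', wanted '", want, "'")
  }

  strainNames <- uniqueSpec$strain
  strainGenomes <- vapply(seq_along(strainNames), function(i) {
    g <- seqChr
    shared <- truth[truth$strain == "ALL", , drop = FALSE]
    for (r in seq_len(nrow(shared)))
      g <- replaceAt(g, shared$position[r], shared$alt[r])
    mine <- truth[truth$strain == strainNames[i], , drop = FALSE]
    for (r in seq_len(nrow(mine))) {
      if (mine$kind[r] == "SNV") {
        g <- replaceAt(g, mine$position[r], mine$alt[r])
      } else {
        w <- nchar(mine$ref[r])
        g <- paste0(substr(g, 1L, mine$position[r] - 1L),
                    substr(g, mine$position[r] + w, nchar(g)))
      }
    }
    g
  }, character(1))
  names(strainGenomes) <- strainNames

  list(strainGenomes = strainGenomes, truth = truth)
}

# Enumerate single-base substitutions in one CDS realizing `effect`.
# Internal codons only (never the start ATG or the stop codon). Coordinates
# and alleles are reported on the forward genome strand.
cdsSubstitutionCandidates <- function(seqChr, feature, effect) {
  st <- GenomicRanges::start(feature); en <- GenomicRanges::end(feature)
  minus <- as.character(GenomicRanges::strand(feature)) == "-"
  cds <- substr(seqChr, st, en)
  if (minus) cds <- revComp(cds)
  nCodon <- nchar(cds) %/% 3L
  out <- list()
  codonIdx <- sample(2:(nCodon - 1L))  # random scan order
  for (ci in codonIdx) {
    codon <- substr(cds, 3L * ci - 2L, 3L * ci)
    refAa <- translateCodon(codon)
    for (cp in 1:3) {
      refBase <- substr(codon, cp, cp)
      for (alt in setdiff(BASES, refBase)) {
        newCodon <- replaceAt(codon, cp, alt)
        altAa <- translateCodon(newCodon)
        cls <- if (altAa == refAa) "synonymous"
               else if (altAa == "*") unname(STOP_CODONS[newCodon])
               else "missense"
        match <- switch(effect,
          synonymous = cls == "synonymous",
          missense = cls == "missense",
          stop_gain = altAa == "*",
          stop_gain_amber = cls == "stop_gain_amber",
          FALSE)
        if (!match) next
        offset <- 3L * (ci - 1L) + cp  # 1-based offset in coding sequence
        if (minus) {
          gpos <- en - offset + 1L
          out[[length(out) + 1L]] <- data.frame(
            position = gpos, ref = complementBase(refBase),
            alt = complementBase(alt), stringsAsFactors = FALSE)
        } else {
          out[[length(out) + 1L]] <- data.frame(
            position = st + offset - 1L, ref = refBase, alt = alt,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(out) >= 8L) break  # enough choice from this codon scan
  }
  if (length(out) == 0) return(data.frame(position = integer(0),
                                          ref = character(0), alt = character(0)))
  do.call(rbind, out)
}

#' Simulate single-end reads from a strain genome
#'
#' Draws reads uniformly over valid start positions, assigns forward or
#' reverse-complement orientation with probability 1/2, and substitutes each
#' base independently with probability `errorRate` (to a uniformly chosen
#' different base). The read count is `round(meanDepth * L / readLength)`
#' where `L` is the strain genome length, so expected per-base depth equals
#' `meanDepth`.
#'
#' @param strainGenome character(1) or `DNAString`: the strain genome.
#' @param config a [SimulationConfig-class] (read length, depth, error rate).
#' @param strainId label used in read names.
#' @param seed integer seed for this strain (defaults to the config seed).
#' @return A [Biostrings::DNAStringSet] of reads; metadata columns
#'   `origin` (1-based start in the strain genome) and `strand` record the
#'   true provenance of each read.
#' @export
simulateReads <- function(strainGenome, config, strainId = "strain",
                          seed = config@seed) {
  set.seed(seed)
  g <- as.character(strainGenome)
  L <- nchar(g)
  rl <- config@readLength
  n <- round(config@meanDepth * L / rl)
  starts <- sample.int(L - rl + 1L, n, replace = TRUE)
  minus <- sample(c(FALSE, TRUE), n, replace = TRUE)
  seqs <- substring(g, starts, starts + rl - 1L)
  if (any(minus)) seqs[minus] <- revComp(seqs[minus])
  if (config@errorRate > 0) {
    nerr <- stats::rbinom(1L, n * rl, config@errorRate)
    if (nerr > 0) {
      at <- sample.int(n * rl, nerr)
      ri <- (at - 1L) %/% rl + 1L
      off <- (at - 1L) %% rl + 1L
      cur <- substring(seqs[ri], off, off)
      pick <- sample.int(3L, nerr, replace = TRUE)
      for (j in seq_len(nerr)) {
        substr(seqs[ri[j]], off[j], off[j]) <- setdiff(BASES, cur[j])[pick[j]]
      }
    }
  }
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- sprintf("%s_r%07d", strainId, seq_len(n))
  S4Vectors::mcols(reads) <- S4Vectors::DataFrame(
    origin = starts, strand = ifelse(minus, "-", "+"))
  reads
}
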