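test_that("reference generation is deterministic and matches the config", {
  cfg <- SimulationConfig(genomeLength = 50000, geneCount = 20, trnaCount = 1,
                          seed = 1)
  ref1 <- generateReference(cfg)
  ref2 <- generateReference(cfg)
  expect_equal(genomeLength(ref1$genome), 50000L)
  expect_identical(refSequence(ref1$genome, as.character = TRUE),
                   refSequence(ref2$genome, as.character = TRUE))
  expect_identical(as.data.frame(ref1$features), as.data.frame(ref2$features))
  md <- S4Vectors::mcols(ref1$features)
  expect_equal(sum(md$kind == "CDS"), 20)
  expect_equal(sum(md$kind == "tRNA"), 1)
  expect_true(validateFeatures(ref1$features, ref1$genome))
  # exactly one tRNA with the CGA anticodon, readable in stored orientation
  ti <- which(md$kind == "tRNA")
  acStart <- GenomicRanges::start(ref1$features)[ti] + md$anticodon_offset[ti]
  anticodon <- substr(refSequence(ref1$genome, TRUE), acStart, acStart + 2)
  expect_equal(anticodon, "CGA")
})

test_that("feature requests that cannot fit raise a sizing error", {
  cfg <- SimulationConfig(genomeLength = 5000, geneCount = 20, trnaCount = 1,
                          seed = 1)
  expect_error(generateReference(cfg), "sizing error")
})

test_that("implanted variants agree with the truth table and strain genomes", {
  cfg <- smallScenario(seed = 3)
  ref <- generateReference(cfg)
  imp <- implantVariants(ref$genome, ref$features, cfg@sharedSpec,
                         cfg@uniqueSpec, seed = 99)
  truth <- imp$truth
  refChr <- refSequence(ref$genome, as.character = TRUE)

  # one private variant per non-NONE strain, shared rows marked ALL/parental
  expect_true(all(truth$strain[truth$class == "parental"] == "ALL"))
  expect_true(all(table(truth$strain[truth$class == "unique"]) == 1))

  # ref alleles match the reference at every implanted site
  for (i in seq_len(nrow(truth)))
    expect_equal(substr(refChr, truth$position[i],
                        truth$position[i] + nchar(truth$ref[i]) - 1),
                 truth$ref[i])

  # strain genomes carry all shared SNVs plus exactly their own variant,
  # accounting for the coordinate shift a private deletion introduces
  for (s in names(imp$strainGenomes)) {
    g <- imp$strainGenomes[[s]]
    mine <- truth[truth$strain == s, , drop = FALSE]
    delAt <- if (any(mine$kind == "DEL")) mine$position[mine$kind == "DEL"] else Inf
    delLen <- if (is.finite(delAt)) nchar(mine$ref[mine$kind == "DEL"]) else 0L
    shift <- function(p) ifelse(p > delAt, p - delLen, p)
    for (i in which(truth$strain == "ALL"))
      expect_equal(substr(g, shift(truth$position[i]), shift(truth$position[i])),
                   truth$alt[i])
    if (is.finite(delAt)) expect_equal(nchar(g), nchar(refChr) - delLen)
    snv <- mine[mine$kind == "SNV", , drop = FALSE]
    for (i in seq_len(nrow(snv)))
      expect_equal(substr(g, snv$position[i], snv$position[i]), snv$alt[i])
  }

  # effect consistency: the annotation module reproduces the intended effect
  for (i in which(truth$kind == "SNV")) {
    eff <- annotateVariant(truth$position[i], truth$ref[i], truth$alt[i],
                           ref$features, ref$genome)
    want <- truth$effect[i]
    expect_true(switch(want,
      intergenic = eff$effect_class == "intergenic",
      synonymous = eff$effect_class == "synonymous",
      missense = eff$effect_class == "missense",
      anticodon = eff$effect_class == "anticodon_change",
      stop_gain = grepl("^stop_gain", eff$effect_class),
      stop_gain_amber = eff$effect_class == "stop_gain_amber",
      FALSE), label = paste(want, "->", eff$effect_class))
  }

  # implanted sites are at least one read length apart
  pos <- sort(truth$position)
  expect_true(all(diff(pos) >= 36))
})

test_that("unrealizable effect requests fail with a construction error", {
  cfg <- smallScenario()
  ref <- generateReference(cfg)
  us <- data.frame(strain = "sA", kind = "SNV", effect = "stop_gain_amber",
                   essential = TRUE, stringsAsFactors = FALSE)
  noEssential <- ref$features
  S4Vectors::mcols(noEssential)$essential <- FALSE
  expect_error(
    implantVariants(ref$genome, noEssential, character(0), us, seed = 1),
    "effect-construction error")
})

test_that("read simulation honours the coverage identity and provenance", {
  cfg <- SimulationConfig(genomeLength = 50000, geneCount = 2, trnaCount = 1,
                          meanDepth = 30, readLength = 36, errorRate = 0,
                          seed = 5)
  ref <- generateReference(cfg)
  g <- refSequence(ref$genome, as.character = TRUE)
  reads <- simulateReads(g, cfg, strainId = "s", seed = 5)
  expect_equal(length(reads), 41667L)  # round(30 * 50000 / 36)
  again <- simulateReads(g, cfg, strainId = "s", seed = 5)
  expect_identical(as.character(reads), as.character(again))

  # zero-noise limit: every read is an exact substring at its origin
  md <- S4Vectors::mcols(reads)
  idx <- sample.int(length(reads), 300)
  for (i in idx) {
    want <- substr(g, md$origin[i], md$origin[i] + 35)
    got <- as.character(reads[[i]])
    if (md$strand[i] == "-") got <- oracleRevComp(got)
    expect_identical(got, want)
  }

  # mean observed per-base depth near the configured 30X
  cfgSmall <- SimulationConfig(genomeLength = 4000, geneCount = 1,
                               trnaCount = 1, meanDepth = 30, errorRate = 0,
                               seed = 1)
  refS <- generateReference(cfgSmall)
  gS <- refSequence(refS$genome, as.character = TRUE)
  depths <- vapply(1:5, function(s) {
    r <- simulateReads(gS, cfgSmall, seed = s)
    m <- S4Vectors::mcols(r)
    cov <- integer(nchar(gS))
    for (i in seq_along(r)) {
      span <- m$origin[i]:(m$origin[i] + 35)
      cov[span] <- cov[span] + 1L
    }
    mean(cov)
  }, numeric(1))
  expect_lt(abs(mean(depths) - 30) / 30, 0.05)

  # substitution errors appear at roughly the configured rate
  cfgErr <- SimulationConfig(genomeLength = 4000, geneCount = 1, trnaCount = 1,
                             meanDepth = 30, errorRate = 0.01, seed = 2)
  rErr <- simulateReads(gS, cfgErr, seed = 2)
  mErr <- S4Vectors::mcols(rErr)
  nDiff <- 0L
  for (i in seq_along(rErr)) {
    want <- substr(gS, mErr$origin[i], mErr$origin[i] + 35)
    got <- as.character(rErr[[i]])
    if (mErr$strand[i] == "-") got <- oracleRevComp(got)
    nDiff <- nDiff + sum(strsplit(got, "")[[1]] != strsplit(want, "")[[1]])
  }
  rate <- nDiff / (36 * length(rErr))
  expect_lt(abs(rate - 0.01), 0.002)
})
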