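test_that("the k-mer index enumerates positions completely", {
  idx <- buildIndex(ReferenceGenome("ACGTACGT"), k = 4, readLength = 12)
  expect_equal(as.integer(seedHits(idx, "ACGT")), c(1L, 5L))
  expect_equal(length(seedHits(idx, "TTTT")), 0L)
  # every reference position 1..L-k+1 indexed exactly once
  expect_equal(length(idx@positions), 8L - 4L + 1L)
  expect_setequal(idx@positions, 1:5)

  set.seed(42)
  g <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  idx2 <- buildIndex(ReferenceGenome(g), k = 6, readLength = 18)
  expect_equal(length(idx2@positions), 300L - 6L + 1L)
})

test_that("seed lengths breaking the pigeonhole guarantee are rejected", {
  g <- ReferenceGenome(strrep("ACGT", 20))
  expect_error(buildIndex(g, k = 13, readLength = 36), "parameter error")
  expect_error(buildIndex(g, k = 0, readLength = 36), "parameter error")
})

test_that("read triage follows the aligned/suppressed/orphan contract", {
  set.seed(7)
  core <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  dup <- substr(core, 101, 136)            # 36-mer duplicated verbatim
  g <- paste0(core, dup, paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                               collapse = ""))
  genome <- ReferenceGenome(g)
  idx <- buildIndex(genome, k = 12, readLength = 36)

  unique36 <- substr(core, 301, 336)
  hit <- alignRead(unique36, idx, genome)
  expect_equal(hit$status, "aligned")
  expect_equal(hit$position, 301L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$mismatches, 0L)

  # reverse-complement read maps to the same locus on '-'
  rcHit <- alignRead(oracleRevComp(unique36), idx, genome)
  expect_equal(rcHit$status, "aligned")
  expect_equal(rcHit$position, 301L)
  expect_equal(rcHit$strand, "-")

  # read from the duplicated segment: two equally good loci -> suppressed
  expect_equal(alignRead(dup, idx, genome)$status, "suppressed")

  # three substitutions exceed the budget -> orphan
  set.seed(8)
  expect_equal(alignRead(mutateRead(unique36, 3), idx, genome)$status, "orphan")

  # non-ACGT symbols make a read an orphan, not an error
  bad <- paste0("N", substr(unique36, 2, 36))
  expect_equal(suppressMessages(alignRead(bad, idx, genome))$status, "orphan")
})

test_that("suppression is decided among best-mismatch placements only", {
  set.seed(9)
  core <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  seg <- substr(core, 51, 86)
  near <- seg
  substr(near, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(seg, 5, 5))[1]
  substr(near, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(seg, 20, 20))[1]
  genome <- ReferenceGenome(paste0(core, near))  # 2-mismatch copy at 301
  idx <- buildIndex(genome, k = 12, readLength = 36)
  hit <- alignRead(seg, idx, genome)
  # a unique 0-mismatch placement wins despite the 2-mismatch secondary
  expect_equal(hit$status, "aligned")
  expect_equal(hit$position, 51L)
  expect_equal(hit$mismatches, 0L)
})

test_that("seed-and-extend agrees with the exhaustive Hamming oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    L <- 1500
    g <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    genome <- ReferenceGenome(g)
    idx <- buildIndex(genome, k = 12, readLength = 36)
    starts <- sample.int(L - 35, 120, replace = TRUE)
    nSub <- sample(0:3, 120, replace = TRUE)
    minus <- sample(c(TRUE, FALSE), 120, replace = TRUE)
    reads <- vapply(seq_along(starts), function(i) {
      r <- substr(g, starts[i], starts[i] + 35)
      if (minus[i]) r <- oracleRevComp(r)
      mutateRead(r, nSub[i])
    }, character(1))
    got <- alignReadSet(reads, idx, genome)$alignments
    for (i in seq_along(reads)) {
      want <- bruteForceAlign(reads[i], g)
      expect_equal(got$status[i], want$status,
                   label = sprintf("status seed %d read %d", seed, i))
      if (want$status == "aligned") {
        expect_equal(got$position[i], want$position)
        expect_equal(got$strand[i], want$strand)
        expect_equal(got$mismatches[i], want$mismatches)
      }
    }
    # pigeonhole completeness: <=2 substitutions never orphan a read
    recoverable <- nSub <= 2
    expect_true(all(got$status[recoverable] != "orphan"))
  }
})

test_that("triage counts are conserved and percentages follow the counts", {
  cfg <- smallScenario(seed = 21, errorRate = 0.003, meanDepth = 10)
  ref <- generateReference(cfg)
  idx <- buildIndex(ref$genome)
  reads <- simulateReads(refSequence(ref$genome, TRUE), cfg, seed = 4)
  res <- alignReadSet(reads, idx, ref$genome, strainId = "sA")
  st <- res$stats
  expect_equal(st@alignedReads + st@suppressedReads + st@orphanReads,
               st@totalReads)
  df <- as.data.frame(st)
  expect_equal(df$aligned_pct,
               roundHalfUp(100 * st@alignedReads / st@totalReads, 2))
  expect_lt(abs(df$aligned_pct + df$suppressed_pct + df$orphan_pct - 100), 0.02)
  # table row statuses match the stats
  expect_equal(sum(res$alignments$status == "aligned"), st@alignedReads)
})

test_that("an empty read set yields zeroed statistics", {
  genome <- ReferenceGenome(strrep("ACGT", 100))
  idx <- buildIndex(genome)
  res <- alignReadSet(character(0), idx, genome)
  df <- as.data.frame(res$stats)
  expect_equal(df$total_reads, 0)
  expect_equal(df$aligned_pct, 0)
  expect_equal(df$orphan_pct, 0)
})

test_that("approximate depth follows the coverage identity", {
  expect_equal(computeDepth(41667, readLength = 36, genomeLength = 50000), 30L)
  expect_equal(computeDepth(0, readLength = 36, genomeLength = 50000), 0L)
  st <- AlignmentStats("x", 100, 100, 0, 0, readLength = 36,
                       genomeLength = 1200)
  expect_equal(computeDepth(st), 3L)
})
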