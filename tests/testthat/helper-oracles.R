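# Independent oracles and shared fixtures. The oracles deliberately avoid
# the package's seed-and-extend / vectorized code paths: alignment is an
# exhaustive all-positions-both-strands Hamming scan, and calling is a
# plain per-column recount.

oracleRevComp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# exhaustive alignment of one read: scan every position on both strands
bruteForceAlign <- function(read, genomeChr, maxMismatch = 2) {
  g <- strsplit(genomeChr, "")[[1]]
  L <- length(g)
  n <- nchar(read)
  win <- matrix(g[outer(seq_len(n) - 1L, 0:(L - n), "+") + 1L], nrow = n)
  hits <- list()
  for (orient in c("+", "-")) {
    s <- if (orient == "+") read else oracleRevComp(read)
    rv <- strsplit(s, "")[[1]]
    mm <- colSums(win != rv)
    at <- which(mm <= maxMismatch)
    if (length(at))
      hits[[orient]] <- data.frame(position = at, strand = orient,
                                   mism = mm[at], stringsAsFactors = FALSE)
  }
  pl <- do.call(rbind, hits)
  if (is.null(pl) || nrow(pl) == 0)
    return(list(status = "orphan", position = NA_integer_,
                strand = NA_character_, mismatches = NA_integer_))
  best <- min(pl$mism)
  bestRows <- pl[pl$mism == best, , drop = FALSE]
  if (nrow(bestRows) == 1L)
    list(status = "aligned", position = bestRows$position,
         strand = bestRows$strand, mismatches = best)
  else
    list(status = "suppressed", position = NA_integer_,
         strand = NA_character_, mismatches = NA_integer_)
}

# independent recount of the consensus-calling rule, one column at a time
recountCalls <- function(pileup, refChars, minFraction = 0.99, minDepth = 10) {
  out <- list()
  for (p in seq_len(ncol(pileup))) {
    counts <- pileup[, p]
    depth <- sum(counts)
    if (depth < minDepth || depth == 0) next
    mx <- max(counts)
    b <- c("A", "C", "G", "T")[which(counts == mx)[1]]
    if (b == refChars[p]) next
    if (mx / depth >= minFraction) out[[length(out) + 1L]] <-
      data.frame(position = p, alt = b, support = mx / depth)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(position = integer(0), alt = character(0), support = numeric(0))
}

# inject k substitutions into a read at distinct offsets
mutateRead <- function(read, k) {
  if (k == 0) return(read)
  at <- sample.int(nchar(read), k)
  for (p in at) {
    cur <- substr(read, p, p)
    substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  read
}

# small pipeline scenario used across tests: 3 strains, noise-free reads.
# 25X keeps every site comfortably above the caller's depth-10 floor.
smallScenario <- function(seed = 11, errorRate = 0, meanDepth = 25) {
  PipelineConfig(
    genomeLength = 12000, geneCount = 4, trnaCount = 1, nStrains = 3,
    sharedSpec = c("anticodon", "missense", "intergenic"),
    uniqueSpec = data.frame(
      strain = c("sA", "sB", "sC"),
      kind = c("SNV", "DEL", "SNV"),
      effect = c("missense", "intergenic", "stop_gain_amber"),
      essential = c(NA, NA, TRUE), stringsAsFactors = FALSE),
    meanDepth = meanDepth, errorRate = errorRate, seed = seed)
}

# one full standard-scenario run, computed once per test session
standardRunCached <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 0) {
    key <- paste0("run", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- suppressMessages(
        runPipeline(standardScenario(seed = seed), verbose = FALSE))
    cache[[key]]
  }
})
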