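# Null-model construction: positional, genome, and the two comparison
# randomisers.

test_that("positional placements match the brute-force valid-start set", {
  # one gene at [400,500) (0-based), TAD of length 200 containing it:
  # valid starts are exactly {300..400} by enumeration
  gm <- toyGenome(genesDf(c("g1", "chr1", 400, 500)), c(chr1 = 1000))
  ts <- TADSet(tadsDf(c("chr1", 300, 500, "T")), style = "partition")
  valid <- enumValidStarts(1000, 200, 401, 500, 1)
  expect_identical(valid, 300:400)
  for (s in 1:50) {
    r <- randomizePositional(ts, gm, seed = s)
    gr <- tads(r)
    expect_equal(length(gr), 1L)
    expect_equal(width(gr), 200L)
    expect_true((start(gr) - 1) %in% valid)
  }
})

test_that("zero-gene TADs relocate anywhere with length preserved", {
  gm <- toyGenome(genesDf(c("g1", "chr2", 10, 20)),
                  c(chr1 = 1000, chr2 = 1000))
  ts <- TADSet(tadsDf(c("chr1", 100, 300, "T")), style = "partition")
  starts <- vapply(1:60, function(s)
    start(tads(randomizePositional(ts, gm, seed = s))) - 1, numeric(1))
  expect_true(all(starts >= 0 & starts <= 800))
  expect_gt(length(unique(starts)), 10)
})

test_that("fully constrained partition fixture reproduces the original set", {
  # each chromosome is exactly as long as its TAD: the only admissible
  # placement is the original one, whatever the shuffle order
  gm <- toyGenome(genesDf(c("a", "chr1", 10, 30),
                          c("b", "chr2", 110, 130),
                          c("c", "chr2", 150, 170)),
                  c(chr1 = 100, chr2 = 200, chr3 = 150))
  ts <- TADSet(tadsDf(c("chr1", 0, 100, "T1"), c("chr2", 0, 200, "T2"),
                      c("chr3", 0, 150, "T3")), style = "partition")
  for (s in 1:5) {
    r <- tads(randomizePositional(ts, gm, seed = s))
    expect_equal(length(r), 3L)
    expect_equal(start(r) - 1, c(0, 0, 0))
    expect_equal(unname(width(r)), c(100L, 200L, 150L))
  }
})

test_that("emitted positional TADs always match chromosome, length and gene count", {
  for (seed in 1:3) {
    d <- simulateAll(simulationConfig(seed = seed, nChromosomes = 2,
                                      nGenesPerChromosome = 20))
    src <- tads(d$tads)
    srcCounts <- setNames(geneCounts(d$tads, d$genome), src$tad_id)
    srcChrom <- setNames(as.character(seqnames(src)), src$tad_id)
    srcLen <- setNames(width(src), src$tad_id)
    r <- randomizePositional(d$tads, d$genome, seed = seed + 100)
    gr <- tads(r)
    rc <- geneCounts(r, d$genome)
    expect_identical(unname(rc), unname(srcCounts[gr$source_id]))
    expect_identical(as.character(seqnames(gr)),
                     unname(srcChrom[gr$source_id]))
    expect_identical(unname(width(gr)), unname(srcLen[gr$source_id]))
  }
})

test_that("overlapping style with nonNestedProb = 0 emits only nested overlaps", {
  d <- simulateAll(simulationConfig(seed = 4, tadStyle = "overlapping",
                                    nestingRate = 0.6))
  r <- randomizePositional(d$tads, d$genome, nonNestedProb = 0, seed = 9)
  gr <- tads(r)
  chr <- as.character(seqnames(gr))
  s <- start(gr); e <- end(gr)
  for (i in seq_along(gr)) {
    ov <- which(chr == chr[i] & s <= e[i] & e >= s[i])
    ov <- setdiff(ov, i)
    for (j in ov) {
      nested <- (s[i] >= s[j] && e[i] <= e[j]) ||
                (s[j] >= s[i] && e[j] <= e[i])
      expect_true(nested)
    }
  }
})

test_that("genome randomisation preserves coordinates, ids and per-TAD counts", {
  d <- simulateAll(simulationConfig(seed = 5))
  g0 <- genes(d$genome)
  perm <- randomizeGenome(d$genome, seed = 42)
  g1 <- genes(perm)
  expect_identical(start(g0), start(g1))
  expect_identical(end(g0), end(g1))
  for (c in unique(as.character(seqnames(g0)))) {
    i <- as.character(seqnames(g0)) == c
    expect_setequal(g0$gene_id[i], g1$gene_id[i])
  }
  expect_identical(geneCounts(d$tads, d$genome),
                   geneCounts(d$tads, perm))
  # single-gene chromosome: identity permutation
  gm1 <- toyGenome(genesDf(c("only", "chr1", 10, 20)))
  expect_identical(genes(randomizeGenome(gm1, seed = 1))$gene_id, "only")
  # closure: composing two permutations is again a permutation
  perm2 <- randomizeGenome(perm, seed = 43)
  expect_setequal(genes(perm2)$gene_id, g0$gene_id)
})

test_that("3-gene permutation frequencies are uniform over the 6 permutations", {
  gm <- toyGenome(genesDf(c("a", "chr1", 0, 10), c("b", "chr1", 20, 30),
                          c("c", "chr1", 40, 50)), c(chr1 = 100))
  draws <- vapply(1:1500, function(s)
    paste(genes(randomizeGenome(gm, seed = s))$gene_id, collapse = ""),
    character(1))
  tab <- table(draws)
  expect_equal(length(tab), 6L)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("span-based comparison randomiser shrinks and skips zero-gene TADs", {
  # genes spaced much closer than the source TAD length: every emitted
  # span must be shorter than the source
  gm <- toyGenome(genesDf(c("a", "chr1", 100, 110), c("b", "chr1", 150, 160),
                          c("c", "chr1", 300, 310), c("d", "chr1", 330, 340)),
                  c(chr1 = 2000))
  ts <- TADSet(tadsDf(c("chr1", 50, 250, "T1"),        # genes a,b; len 200
                      c("chr1", 1200, 1500, "T0")),    # zero genes
               style = "partition")
  # every 2-gene run spans well under 200 bp, so emitted < source always
  expect_message(r <- randomizeNora(ts, gm, seed = 3), "skipped 1 zero-gene")
  gr <- tads(r)
  expect_equal(length(gr), 1L)                          # T0 skipped
  expect_lt(width(gr), 200)                             # strictly shorter
  expect_equal(unname(geneCounts(r, gm)), 2L)
  # property over seeds: emitted length <= source, count preserved
  for (s in 1:20) {
    rr <- suppressMessages(randomizeNora(ts, gm, seed = s))
    expect_true(all(width(tads(rr)) <= 200))
    expect_true(all(geneCounts(rr, gm) == 2L))
  }
})

test_that("gap-avoiding randomiser is uniform without gaps and respects gaps", {
  gm <- toyGenome(genesDf(c("g", "chr1", 400, 500)), c(chr1 = 1000))
  ts <- TADSet(tadsDf(c("chr1", 100, 300, "T")), style = "partition")
  # no gaps: uniform over all starts 0..800 (gene count unconstrained)
  starts <- vapply(1:800, function(s)
    start(tads(randomizeRao(ts, gm, seed = s))) - 1, numeric(1))
  expect_true(all(starts >= 0 & starts <= 800))
  h <- table(cut(starts, breaks = seq(0, 800, by = 100),
                 include.lowest = TRUE))
  expect_gt(chisq.test(h)$p.value, 0.01)
  # gene counts may differ from the source's
  cnts <- vapply(1:50, function(s)
    geneCounts(randomizeRao(ts, gm, seed = s), gm), integer(1))
  expect_true(any(cnts == 1L) && any(cnts == 0L))
  # gap covering all but one window: deterministic placement at start 800
  gaps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 800))
  for (s in c(7, 8, 9)) {
    r <- randomizeRao(ts, gm, gaps = gaps, seed = s)
    expect_equal(start(tads(r)) - 1, 800)
  }
})

test_that("ensembles are reproducible from the master seed", {
  d <- simulateAll(simulationConfig(seed = 6, nGenesPerChromosome = 15))
  e1 <- buildEnsemble(d$tads, d$genome, "positional", nSets = 5, seed = 11)
  e2 <- buildEnsemble(d$tads, d$genome, "positional", nSets = 5, seed = 11)
  expect_identical(lapply(nullSets(e1), function(s) as.data.frame(tads(s))),
                   lapply(nullSets(e2), function(s) as.data.frame(tads(s))))
  expect_identical(setSeeds(e1), setSeeds(e2))
  e3 <- buildEnsemble(d$tads, d$genome, "positional", nSets = 5, seed = 12)
  expect_false(identical(as.data.frame(tads(nullSets(e1)[[1]])),
                         as.data.frame(tads(nullSets(e3)[[1]]))))
  expect_equal(length(nullSets(e1)), 5L)
  expect_length(excludedCounts(e1), 5L)
})

test_that("a TAD longer than its chromosome is excluded with a warning", {
  gm <- toyGenome(genesDf(c("g", "chr1", 10, 20)), c(chr1 = 500))
  ts <- TADSet(tadsDf(c("chr1", 0, 100, "ok"), c("chr1", 0, 490, "big")),
               style = "overlapping")
  # impossible: requires a 600 bp TAD; build directly to bypass bounds
  gr <- tads(ts)
  gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 600),
                                tad_id = "huge")
  tsBig <- TADSet(c(gr, gr2), style = "overlapping")
  expect_warning(r <- randomizePositional(tsBig, gm, seed = 1),
                 "longer than chromosome")
  expect_equal(S4Vectors::metadata(tads(r))$excluded, 1L)
})

test_that("running median of per-set summaries stabilises within the ensemble", {
  d <- simulateAll(simulationConfig(seed = 8))
  ens <- buildEnsemble(d$tads, d$genome, "positional", nSets = 20, seed = 2)
  med <- vapply(nullSets(ens), function(s)
    median(enumerateTadPairs(s, d$genome)$distance), numeric(1))
  rep <- convergenceReport(med, tol = diff(range(med)) / 4)
  expect_length(rep$trace, 20L)
  expect_false(is.na(rep$stabilizationIndex))
  expect_lt(rep$stabilizationIndex, 20L)
  # oscillation envelope of the running median shrinks
  dev <- abs(rep$trace - rep$finalMedian)
  half <- length(dev) %/% 2
  expect_lte(max(dev[(half + 1):length(dev)]), max(dev[1:half]))
})
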