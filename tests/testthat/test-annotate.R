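# Gene assignment, CTCF/compartment classification, occupancy,
# distances, constraint aggregation, concordance.

test_that("strict containment assigns genes, drops straddlers, handles nesting", {
  gm <- toyGenome(genesDf(c("in", "chr1", 150, 200),
                          c("straddle", "chr1", 250, 350),
                          c("deep", "chr1", 255, 300)),
                  c(chr1 = 2000))
  ts <- TADSet(tadsDf(c("chr1", 100, 300, "outer"),
                      c("chr1", 200, 400, "inner")),
               style = "overlapping")
  map <- assignGenes(ts, gm)
  expect_setequal(map$byTad$outer, c("in", "deep"))
  expect_setequal(map$byTad$inner, c("straddle", "deep"))
  expect_setequal(map$byGene$deep, c("outer", "inner"))  # nested: both
  # straddler of 'outer' is not in 'outer'
  expect_false("straddle" %in% map$byTad$outer)
  expect_identical(unname(geneCounts(ts, gm)), c(2L, 2L))
})

test_that("assignment is monotone under TAD enlargement/shrinkage", {
  for (seed in 1:10) {
    fx <- randomPairFixture(seed)
    ts <- fx$tadset
    gr <- tads(ts)
    bigger <- TADSet(data.frame(chrom = as.character(seqnames(gr)),
                                start = pmax(1, start(gr) - 50),
                                end = end(gr) + 50,
                                tad_id = gr$tad_id),
                     style = "overlapping")
    m0 <- assignGenes(ts, fx$genome)
    m1 <- assignGenes(bigger, fx$genome)
    for (t in names(m0$byTad))
      expect_true(all(m0$byTad[[t]] %in% m1$byTad[[t]]))
  }
})

test_that("CTCF classification follows the boundary-window rule", {
  ts <- TADSet(tadsDf(c("chr1", 100000, 300000, "T")), style = "partition")
  both <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(95001, 305001), c(96000, 306000)))
  expect_equal(classifyCtcf(ts, both, 10000)$ctcf_class, "CTCF")
  left <- both[1]
  expect_equal(classifyCtcf(ts, left, 10000)$ctcf_class, "nonCTCF_one")
  none <- GenomicRanges::GRanges("chr1", IRanges::IRanges(700001, 700100))
  expect_equal(classifyCtcf(ts, none, 10000)$ctcf_class, "nonCTCF_zero")
  # window 0: only a peak covering the exact boundary coordinate counts
  atBoundary <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(99901, 299951), c(100200, 300100)))
  expect_equal(classifyCtcf(ts, atBoundary, 0)$ctcf_class, "CTCF")
  nearMiss <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(99000, 299000), c(99900, 299900)))
  expect_equal(classifyCtcf(ts, nearMiss, 0)$ctcf_class, "nonCTCF_zero")
})

test_that("CTCF set is monotone in the window size", {
  d <- simulateAll(simulationConfig(seed = 11, pCtcf = 0.5))
  c1 <- classifyCtcf(d$tads, d$peaks, 5000)
  c2 <- classifyCtcf(d$tads, d$peaks, 20000)
  in1 <- c1$tad_id[c1$ctcf_class == "CTCF"]
  in2 <- c2$tad_id[c2$ctcf_class == "CTCF"]
  expect_true(all(in1 %in% in2))
})

test_that("compartment assignment is by majority overlap with tie -> unassigned", {
  track <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 1001), c(1000, 2000)))
  track$compartment <- c("A", "B")
  fullA <- TADSet(tadsDf(c("chr1", 100, 900)), style = "partition")
  expect_equal(assignCompartment(fullA, track)$compartment, "A")
  tie <- TADSet(tadsDf(c("chr1", 800, 1200)), style = "partition")
  expect_equal(assignCompartment(tie, track)$compartment, "unassigned")
  mostlyB <- TADSet(tadsDf(c("chr1", 800, 1300)), style = "partition")
  expect_equal(assignCompartment(mostlyB, track)$compartment, "B")
  outside <- TADSet(tadsDf(c("chr1", 3000, 3500)), style = "partition")
  expect_equal(assignCompartment(outside, track)$compartment, "unassigned")
})

test_that("occupancy classes collapse at 6+ and exclude zero-gene TADs", {
  counts <- c(0L, 1L, 2L, 5L, 6L, 7L, 12L)
  expect_message(cls <- occupancyClasses(counts), "1 zero-gene")
  expect_equal(as.character(cls),
               c(NA, "1", "2", "5", "6+", "6+", "6+"))
  # classes partition the non-empty TADs
  expect_equal(sum(table(cls)), sum(counts > 0))
})

test_that("intergene distances pool deduplicated start-to-start distances", {
  gm <- toyGenome(genesDf(c("a", "chr1", 100, 110), c("b", "chr1", 200, 210),
                          c("c", "chr1", 400, 410), c("lone", "chr1", 800, 810)),
                  c(chr1 = 2000))
  ts <- TADSet(tadsDf(c("chr1", 50, 500, "T"), c("chr1", 700, 900, "S")),
               style = "partition")
  d <- intergeneDistances(ts, gm)
  expect_setequal(d, c(100, 300, 200))
  expect_equal(median(d), 200)
  # identical-start genes give distance 0
  gm2 <- toyGenome(genesDf(c("x", "chr1", 100, 120), c("y", "chr1", 100, 140)),
                   c(chr1 = 1000))
  ts2 <- TADSet(tadsDf(c("chr1", 0, 200)), style = "partition")
  expect_equal(intergeneDistances(ts2, gm2), 0)
})

test_that("mean constraint pools all transcripts of all contained genes", {
  gm <- toyGenome(genesDf(c("A", "chr1", 100, 150), c("B", "chr1", 200, 250),
                          c("solo", "chr1", 500, 550),
                          c("unscored", "chr1", 700, 750)),
                  c(chr1 = 1000))
  ts <- TADSet(tadsDf(c("chr1", 50, 300, "T1"), c("chr1", 450, 600, "T2"),
                      c("chr1", 650, 800, "T3")), style = "partition")
  corpus <- AnnotationCorpus(constraint = data.frame(
    transcript_id = c("tA1", "tA2", "tB1", "tS1"),
    gene_id = c("A", "A", "B", "solo"),
    score = c(1, 3, 2, 4.2), stringsAsFactors = FALSE))
  mc <- meanConstraint(ts, gm, corpus)
  expect_equal(mc$mean_constraint[mc$tad_id == "T1"], 2)     # mean(1,3,2)
  expect_equal(mc$mean_constraint[mc$tad_id == "T2"], 4.2)
  expect_false("T3" %in% mc$tad_id)                          # no scores
  expect_equal(attr(mc, "n_excluded"), 1L)
  # per-gene-mean variant averages within gene first
  mg <- meanConstraint(ts, gm, corpus, perGeneMean = TRUE)
  expect_equal(mg$mean_constraint[mg$tad_id == "T1"], mean(c(2, 2)))
})

test_that("caller concordance uses the two-bin boundary tolerance, both ways", {
  a <- TADSet(tadsDf(c("chr1", 100000, 300000), c("chr1", 400000, 600000)),
              style = "partition")
  expect_equal(callerConcordance(a, a), list(a_in_b = 1, b_in_a = 1))
  shifted <- TADSet(tadsDf(c("chr1", 120000, 320000),
                           c("chr1", 420000, 620000)), style = "partition")
  cc <- callerConcordance(a, shifted, toleranceBins = 2, binSize = 10000)
  expect_equal(cc$a_in_b, 1)                      # exactly 20 kb shift
  cc1 <- callerConcordance(a, shifted, toleranceBins = 1, binSize = 10000)
  expect_equal(cc1$a_in_b, 0)
  far <- TADSet(tadsDf(c("chr2", 0, 100000)), style = "partition")
  expect_equal(callerConcordance(a, far)$a_in_b, 0)
})

test_that("genome permutation leaves occupancy and distance distributions intact", {
  d <- simulateAll(simulationConfig(seed = 13))
  perm <- randomizeGenome(d$genome, seed = 99)
  expect_identical(sort(geneCounts(d$tads, d$genome)),
                   sort(geneCounts(d$tads, perm)))
  expect_identical(sort(intergeneDistances(d$tads, d$genome)),
                   sort(intergeneDistances(d$tads, perm)))
})

test_that("the singleton constraint gap attenuates under genome randomisation", {
  # planted shift: singleton TADs higher; permuting identities should
  # shrink the observed gap toward 0 in most seeds (sign test)
  hits <- 0L
  nSeeds <- 20L
  for (s in seq_len(nSeeds)) {
    d <- suppressWarnings(
      simulateAll(simulationConfig(seed = s, singletonShift = 2,
                                   nGenesPerChromosome = 20)))
    gap <- function(gen) {
      mc <- meanConstraint(d$tads, gen, d$corpus)
      cnt <- setNames(geneCounts(d$tads, gen), tads(d$tads)$tad_id)
      g1 <- mc$mean_constraint[cnt[mc$tad_id] == 1]
      g2 <- mc$mean_constraint[cnt[mc$tad_id] > 1]
      if (!length(g1) || !length(g2)) return(NA_real_)
      mean(g1) - mean(g2)
    }
    realGap <- gap(d$genome)
    permGap <- gap(randomizeGenome(d$genome, seed = 1000 + s))
    if (!is.na(realGap) && !is.na(permGap) &&
        abs(permGap) < abs(realGap)) hits <- hits + 1L
  }
  expect_gt(hits, nSeeds * 0.5)   # sign test: attenuation in most seeds
})

test_that("annotateTads combines all per-TAD annotations", {
  d <- simulateAll(simulationConfig(seed = 14))
  tab <- annotateTads(d$tads, d$genome, peaks = d$peaks,
                      track = d$compartments, corpus = d$corpus)
  expect_equal(nrow(tab), length(tads(d$tads)))
  expect_true(all(c("n_genes", "occupancy_class", "ctcf_class",
                    "compartment", "mean_constraint") %in% names(tab)))
  expect_true(all(tab$ctcf_class %in%
                  c("CTCF", "nonCTCF_one", "nonCTCF_zero")))
})
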