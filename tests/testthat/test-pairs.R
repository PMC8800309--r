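# Pair enumeration, similarity metrics, ontology index, distance bins.

test_that("pair enumeration follows the nested/overlap deduplication rules", {
  gm <- toyGenome(genesDf(c("a", "chr1", 50, 60), c("b", "chr1", 250, 260),
                          c("c", "chr1", 300, 310)), c(chr1 = 2000))
  # nested: T2 inside T1; (b,c) counted once, from the enclosing TAD
  nested <- TADSet(tadsDf(c("chr1", 0, 1000, "T1"), c("chr1", 200, 400, "T2")),
                   style = "overlapping")
  p <- enumerateTadPairs(nested, gm)
  expect_setequal(paste(p$gene_a, p$gene_b),
                  c("a b", "a c", "b c"))
  expect_equal(nrow(p), 3L)
  # partition: pairs only within each TAD
  gm2 <- toyGenome(genesDf(c("a", "chr1", 10, 20), c("b", "chr1", 30, 40),
                           c("c", "chr1", 110, 120), c("d", "chr1", 130, 140)),
                   c(chr1 = 1000))
  part <- TADSet(tadsDf(c("chr1", 0, 100), c("chr1", 100, 200)),
                 style = "partition")
  p2 <- enumerateTadPairs(part, gm2)
  expect_setequal(paste(p2$gene_a, p2$gene_b), c("a b", "c d"))
  # partial overlap: (a,b) and (b,c) but never (a,c)
  gm3 <- toyGenome(genesDf(c("a", "chr1", 10, 20), c("b", "chr1", 120, 130),
                           c("c", "chr1", 220, 230)), c(chr1 = 1000))
  ov <- TADSet(tadsDf(c("chr1", 0, 150, "L"), c("chr1", 100, 250, "R")),
               style = "overlapping")
  p3 <- enumerateTadPairs(ov, gm3)
  expect_setequal(paste(p3$gene_a, p3$gene_b), c("a b", "b c"))
})

test_that("pair enumeration equals the brute-force co-residence oracle", {
  for (seed in 1:40) {
    fx <- randomPairFixture(seed)
    p <- enumerateTadPairs(fx$tadset, fx$genome)
    expect_identical(sort(paste(p$gene_a, p$gene_b)),
                     bruteForcePairKeys(fx$genes, fx$tads),
                     info = sprintf("fixture seed %d", seed))
  }
})

test_that("paralog flagging, filtering and enrichment counts", {
  corpus <- AnnotationCorpus(paralogPairs = data.frame(
    gene_a = "a", gene_b = "b", stringsAsFactors = FALSE))
  pairs <- data.frame(gene_a = c("a", "a"), gene_b = c("b", "c"),
                      stringsAsFactors = FALSE)
  fl <- flagParalogs(pairs, corpus)
  expect_equal(fl$is_paralog, c(TRUE, FALSE))
  kept <- filterParalogPairs(pairs, corpus)
  expect_equal(nrow(kept), 1L)
  expect_equal(attr(kept, "n_removed"), 1L)
  expect_identical(filterParalogPairs(pairs, AnnotationCorpus())$gene_b,
                   pairs$gene_b)                       # empty paralog set
  allPar <- data.frame(gene_a = "a", gene_b = "b")
  expect_warning(e <- filterParalogPairs(allPar, corpus), "all pairs")
  expect_equal(nrow(e), 0L)

  tp <- data.frame(is_paralog = c(TRUE, TRUE, TRUE, rep(FALSE, 7)))
  np <- data.frame(is_paralog = c(TRUE, rep(FALSE, 9)))
  m <- paralogEnrichmentCounts(tp, np)
  expect_equal(unname(m), matrix(c(3, 7, 1, 9), 2, byrow = TRUE))
  expect_error(paralogEnrichmentCounts(
    data.frame(is_paralog = logical()), np), "zero total")
})

test_that("coexpression floors FPKM < 1 and computes tie-aware Spearman", {
  expr <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1),
                d = c(0.5, 0.9, 0.2, 0.8), e = c(2, 9, 4, 1))
  colnames(expr) <- paste0("s", 1:4)
  pairs <- data.frame(gene_a = c("a", "a", "d", "a"),
                      gene_b = c("b", "c", "e", "zz"),
                      stringsAsFactors = FALSE)
  suppressMessages(p <- coexpression(pairs, expr))
  expect_equal(p$correlation[1], 1)
  expect_equal(p$correlation[2], -1)
  expect_true(is.na(p$correlation[3]))     # d floors to all-zero: constant
  expect_true(is.na(p$correlation[4]))     # zz absent from the matrix
  expect_error(coexpression(pairs, expr[, 1:3]), "three samples")
  # agreement with stats::cor after flooring, and monotone invariance
  set.seed(1)
  x <- rexp(6) + 1; y <- rexp(6) + 1
  e2 <- rbind(x = x, y = y, x2 = x^2)
  colnames(e2) <- paste0("s", 1:6)
  pr <- data.frame(gene_a = c("x", "x2"), gene_b = c("y", "y"))
  suppressMessages(p2 <- coexpression(pr, e2))
  expect_equal(p2$correlation[1], cor(x, y, method = "spearman"))
  expect_equal(p2$correlation[1], p2$correlation[2])  # monotone transform
})

test_that("ontology index computes true-path IC and detects bad DAGs", {
  idx <- buildOntologyIndex(toyDagCorpus())
  expect_equal(unname(idx@ic["R"]), 0)
  expect_equal(unname(idx@ic[c("A", "B")]), c(1, 1))  # normalised ln2/ln2
  # chain with true-path rule: p(parent) >= p(child)
  corpus <- AnnotationCorpus(
    goAnnotations = list(g1 = "A1", g2 = "A", g3 = "B", g4 = "B"),
    ontologyEdges = data.frame(child = c("A", "B", "A1"),
                               parent = c("R", "R", "A")))
  idx2 <- buildOntologyIndex(corpus)
  # p(A) = 2/4 (g2 direct + g1 via A1), p(A1) = 1/4
  expect_lt(idx2@ic["A"], idx2@ic["A1"])
  # cycle detection
  bad <- AnnotationCorpus(goAnnotations = list(g1 = "A"),
                          ontologyEdges = data.frame(
                            child = c("A", "B", "R"),
                            parent = c("R", "A", "B")))
  expect_error(buildOntologyIndex(bad))
  # zero-frequency term is unusable with a warning
  sparse <- AnnotationCorpus(goAnnotations = list(g1 = "A"),
                             ontologyEdges = data.frame(
                               child = c("A", "B"), parent = c("R", "R")))
  expect_warning(idx3 <- buildOntologyIndex(sparse), "zero corpus frequency")
  expect_true(is.na(idx3@ic["B"]))
})

test_that("Jiang similarity matches hand computations on the toy DAGs", {
  idx <- buildOntologyIndex(toyDagCorpus())
  expect_equal(jiangSimilarity(idx, "A", "A"), 1)      # identical terms
  expect_equal(jiangSimilarity(idx, "A", "B"), 0)      # disjoint leaves
  expect_equal(jiangSimilarity(idx, "A", "B"),
               jiangSimilarity(idx, "B", "A"))         # symmetric
  # deeper DAG with hand-computed normalised ICs:
  # 8 genes; A gets 2 direct + 2 via A1, B gets 4 -> IC(A)=IC(B)=0.5,
  # IC(A1)=1 after normalising by ln4
  corpus <- AnnotationCorpus(
    goAnnotations = list(g1 = "A1", g2 = "A1", g3 = "A", g4 = "A",
                         g5 = "B", g6 = "B", g7 = "B", g8 = "B"),
    ontologyEdges = data.frame(child = c("A", "B", "A1"),
                               parent = c("R", "R", "A")))
  idx2 <- buildOntologyIndex(corpus)
  expect_equal(unname(idx2@ic[c("A", "B", "A1")]), c(0.5, 0.5, 1))
  # parent/child: MICA = parent -> 1 - (0.5 + 1 - 2*0.5) = 0.5
  expect_equal(jiangSimilarity(idx2, "A", "A1"), 0.5)
  # cross-branch: MICA = root -> 1 - min(1, 1.5) = 0
  expect_equal(jiangSimilarity(idx2, "A1", "B"), 0)
  expect_error(jiangSimilarity(idx2, "A", "nope"), "unknown")
})

test_that("gene-level BMA combines term sets and yields NA when unannotated", {
  corpus <- toyDagCorpus()
  idx <- buildOntologyIndex(corpus)
  expect_equal(geneGoSimilarity(idx, corpus, "g1", "g2"), 1)  # same term
  expect_equal(geneGoSimilarity(idx, corpus, "g1", "g3"), 0)  # A vs B
  expect_true(is.na(geneGoSimilarity(idx, corpus, "g1", "absent")))
  # self-similarity of any annotated gene is 1
  for (g in names(corpus@goAnnotations))
    expect_equal(geneGoSimilarity(idx, corpus, g, g), 1)
  pairs <- data.frame(gene_a = c("g1", "g1"), gene_b = c("g2", "g3"))
  p <- goSimilarity(pairs, idx, corpus)
  expect_equal(p$go_sim, c(1, 0))
})

test_that("shared pathway and PPI flags follow the NA-each-side rule", {
  corpus <- AnnotationCorpus(
    pathways = list(a = c("P1", "P2"), b = "P2", c = "P3"),
    ppiEdges = data.frame(gene_a = c("a", "a"), gene_b = c("b", "c"),
                          stringsAsFactors = FALSE))
  pairs <- data.frame(gene_a = c("a", "a", "a", "b"),
                      gene_b = c("b", "c", "nope", "c"),
                      stringsAsFactors = FALSE)
  sp <- sharedPathway(pairs, corpus)
  expect_equal(sp$shares_pathway, c(TRUE, FALSE, NA, FALSE))
  ppi <- sharedPpi(pairs, corpus)
  expect_equal(ppi$shares_ppi[1:2], c(TRUE, TRUE))
  expect_true(is.na(ppi$shares_ppi[3]))        # 'nope' has no edges
  expect_false(ppi$shares_ppi[4])              # b-c not an edge
  # partner mode: b and c share the partner a
  pp <- sharedPpi(pairs, corpus, mode = "partner")
  expect_true(pp$shares_ppi[4])
  # denominator reconciliation: non-NA count equals pairs with both
  # genes annotated
  annotated <- names(corpus@pathways)
  expectNonNA <- pairs$gene_a %in% annotated & pairs$gene_b %in% annotated
  expect_equal(!is.na(sp$shares_pathway), expectNonNA)
})

test_that("metric lookup matrices agree with the per-pair functions", {
  d <- simulateAll(simulationConfig(seed = 21, nGenesPerChromosome = 15))
  idx <- buildOntologyIndex(d$corpus)
  mats <- pairMetricMatrices(d$genome, expr = d$expression,
                             corpus = d$corpus, index = idx)
  pairs <- allGenePairs(d$genome)[1:40, ]
  direct <- pairMetrics(pairs, expr = d$expression, corpus = d$corpus,
                        index = idx)
  ia <- match(pairs$gene_a, mats$ids)
  ib <- match(pairs$gene_b, mats$ids)
  expect_equal(mats$correlation[cbind(ia, ib)], direct$correlation)
  expect_equal(mats$go_sim[cbind(ia, ib)], direct$go_sim)
  expect_equal(mats$shares_pathway[cbind(ia, ib)], direct$shares_pathway)
  expect_equal(mats$shares_ppi[cbind(ia, ib)], direct$shares_ppi)
  expect_equal(mats$is_paralog[cbind(ia, ib)], direct$is_paralog)
})

test_that("distance binning assigns pairs and tests per bin", {
  gm <- toyGenome(genesDf(c("a", "chr1", 0, 10000),
                          c("b", "chr1", 50000, 60000),
                          c("c", "chr1", 500000, 510000)),
                  c(chr1 = 1e6))
  expr <- matrix(rexp(12) + 1, 3, 4,
                 dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  res <- genomewideDistanceBins(gm, expr = expr,
                                binEdges = c(0, 1e5, 1e6),
                                nRandomGenomes = 20, seed = 4)
  # a-b 50 kb apart -> first bin; a-c and b-c in the second
  expect_equal(res$real$n_pairs, c(1L, 2L, 0L))
  expect_true(is.na(res$real$median_correlation[3]))   # empty bin
  expect_true(all(res$p$median_correlation[1:2] >= 0 &
                  res$p$median_correlation[1:2] <= 1, na.rm = TRUE))
  expect_true(is.na(res$p$median_correlation[3]))
  # permutation leaves the pair-count totals unchanged by construction
  expect_equal(sum(res$real$n_pairs), nrow(allGenePairs(gm)))
})
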