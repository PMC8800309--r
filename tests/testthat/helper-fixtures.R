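# Shared fixture builders and independent oracles. Oracles are written
# against the definitions directly (enumeration, closed forms) and share
# no code with the implementation paths they check.

toyGenome <- function(genes, sizes = c(chr1 = 1000)) {
  GenomeModel(genes, sizes)
}

# genes as (id, chrom, start0, end0) in 0-based half-open coordinates,
# converted here to the 1-based inclusive gene-table convention
genesDf <- function(...) {
  m <- rbind(...)
  data.frame(gene_id = m[, 1], chrom = m[, 2],
             start = as.numeric(m[, 3]) + 1, end = as.numeric(m[, 4]),
             stringsAsFactors = FALSE)
}

tadsDf <- function(...) {
  m <- rbind(...)
  df <- data.frame(chrom = m[, 1], start = as.numeric(m[, 2]) + 1,
                   end = as.numeric(m[, 3]), stringsAsFactors = FALSE)
  if (ncol(m) >= 4) df$tad_id <- m[, 4]
  df
}

# Toy GO corpus: root R with children A and B, four genes, two annotated
# to each child. p(A) = p(B) = 0.5, normalised IC(A) = IC(B) = 1.
toyDagCorpus <- function() {
  AnnotationCorpus(
    goAnnotations = list(g1 = "A", g2 = "A", g3 = "B", g4 = "B"),
    ontologyEdges = data.frame(child = c("A", "B"), parent = c("R", "R"),
                               stringsAsFactors = FALSE))
}

# Oracle: brute-force set of unordered gene pairs co-resident in >= 1 TAD
# under strict containment (0-based half-open arithmetic, independent of
# the GRanges path).
bruteForcePairKeys <- function(geneDf1based, tadDf1based) {
  keys <- character()
  for (t in seq_len(nrow(tadDf1based))) {
    inside <- which(geneDf1based$chrom == tadDf1based$chrom[t] &
                    geneDf1based$start >= tadDf1based$start[t] &
                    geneDf1based$end <= tadDf1based$end[t])
    if (length(inside) < 2) next
    ids <- geneDf1based$gene_id[inside]
    cb <- utils::combn(ids, 2L)
    keys <- c(keys, paste(pmin(cb[1L, ], cb[2L, ]),
                          pmax(cb[1L, ], cb[2L, ])))
  }
  sort(unique(keys))
}

# Oracle: all valid 0-based starts for a length-len window on a
# chromosome of length L containing exactly k genes (genes given 1-based
# closed), by full enumeration.
enumValidStarts <- function(L, len, geneStart1, geneEnd1, k) {
  starts <- 0:(L - len)
  ok <- vapply(starts, function(s) {
    sum(geneStart1 >= s + 1 & geneEnd1 <= s + len) == k
  }, logical(1))
  starts[ok]
}

# Oracle: two-sided Fisher p by full fixed-margin hypergeometric
# enumeration (sum of probabilities <= observed, with the usual relative
# tolerance for ties).
fisherEnumOracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1]); c2 <- sum(m[, 2])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, c1, c2, r1)
  pObs <- dhyper(m[1, 1], c1, c2, r1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Oracle: exact two-sided rank-sum p by enumeration of all group
# assignments (tie-free samples only).
exactRankSumOracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(na + nb, na)
  uAll <- apply(sets, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  pLow <- mean(uAll <= uObs)
  pHigh <- mean(uAll >= uObs)
  min(1, 2 * min(pLow, pHigh))
}

# Oracle: Benjamini-Hochberg step-up by the definition.
bhStepUpOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o]
  vals <- sorted * n / seq_len(n)
  vals <- rev(cummin(rev(vals)))
  adj[o] <- pmin(1, vals)
  adj
}

# Random nested/overlapping TAD + gene fixture for the pair-enumeration
# oracle.
randomPairFixture <- function(seed) {
  set.seed(seed)
  L <- 10000
  nGenes <- sample(5:50, 1)
  starts <- sort(sample(0:(L - 20), nGenes))
  lens <- sample(5:15, nGenes, replace = TRUE)
  ends <- pmin(L, starts + lens)
  gdf <- data.frame(gene_id = sprintf("g%02d", seq_len(nGenes)),
                    chrom = "chr1", start = starts + 1, end = ends,
                    stringsAsFactors = FALSE)
  nTads <- sample(3:10, 1)
  ts <- sample(0:(L - 100), nTads, replace = TRUE)
  tl <- sample(50:4000, nTads, replace = TRUE)
  te <- pmin(L, ts + tl)
  tdf <- data.frame(chrom = "chr1", start = ts + 1, end = te,
                    tad_id = sprintf("t%02d", seq_len(nTads)),
                    stringsAsFactors = FALSE)
  list(genes = gdf, tads = tdf,
       genome = GenomeModel(gdf, c(chr1 = L)),
       tadset = TADSet(tdf, style = "overlapping"))
}
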