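# Synthetic genomes with known, planted structure: chromosomes with
# non-overlapping genes, TAD tilings of both styles, boundary-localised
# CTCF peaks, tandem paralog families, copula-based expression with a
# planted within-TAD correlation and a distance-decay component,
# annotation sharing among TAD co-members, and a singleton-TAD constraint
# shift. The generator is the test-fixture factory for the whole package.

#' Simulation configuration
#'
#' Returns a validated configuration list with documented defaults. All
#' probabilities are in [0, 1]; variance shares rhoTad + decayWeight must
#' not exceed 1.
#'
#' @param nChromosomes Number of autosomes (default 2).
#' @param chromosomeLength Chromosome length in bp (default 1e6).
#' @param nGenesPerChromosome Genes per chromosome (default 25).
#' @param geneLengthRange Min/max gene length in bp.
#' @param tadStyle "partition" or "overlapping".
#' @param tadLengthRange Min/max tiled TAD length in bp.
#' @param tadGapRange Min/max inter-TAD gap in bp (gaps create genes that
#'   straddle boundaries, exercising the strict assignment rule).
#' @param nestingRate For overlapping style: probability a tiled TAD gets
#'   one nested child TAD.
#' @param geneLayout "uniform" (default), "clustered" (tandem gene
#'   clusters encapsulated by TADs, as around real gene families) or
#'   "gradient" (density decaying along the chromosome, emulating
#'   gene-rich vs gene-poor regions).
#' @param pCtcf Per-boundary probability of a CTCF peak within one bin.
#' @param binSize Hi-C bin size in bp.
#' @param nParalogFamilies,familySize Paralog family layout.
#' @param tandemFraction Fraction of families placed as consecutive genes
#'   inside one TAD (the tandem-duplication pattern); the rest are
#'   dispersed genome-wide.
#' @param nSamples Expression samples (default 6: two replicates of three
#'   cell states).
#' @param rhoTad Variance share of the shared TAD factor in the latent
#'   expression profile (0 = no planted co-expression).
#' @param rhoTadCtcfOnly Apply the TAD factor only in TADs with CTCF
#'   support at both boundaries.
#' @param decayWeight Variance share of the distance-decaying chromosomal
#'   factor.
#' @param decayScale Correlation length (bp) of that factor.
#' @param floorFraction Expected fraction of FPKM values below 1 (the
#'   analysis floors these to 0).
#' @param sdLog Log-scale sd of the FPKM transform.
#' @param annotationShare Probability a within-TAD pair is forced to share
#'   a GO leaf / pathway / PPI edge.
#' @param backgroundShare Same for background (non-TAD) pairs.
#' @param unannotatedFraction Fraction of genes with no GO/pathway
#'   annotation (exercises the NA paths).
#' @param constraintMean,constraintSd Background transcript score
#'   distribution (nonsynonymous z-score scale).
#' @param singletonShift Constraint shift added to genes that singly
#'   occupy a TAD.
#' @param pseudoOlfactory Add one large masked gene family occupying a
#'   single TAD (the many-gene-TAD pattern of real olfactory clusters).
#' @param seed Integer seed; one seed reproduces every output exactly.
#' @return A list of class "SimulationConfig".
#' @export
simulationConfig <- function(nChromosomes = 2, chromosomeLength = 1e6,
                             nGenesPerChromosome = 25,
                             geneLengthRange = c(2000, 8000),
                             tadStyle = c("partition", "overlapping"),
                             tadLengthRange = c(40000, 80000),
                             tadGapRange = c(20000, 40000),
                             nestingRate = 0.3,
                             geneLayout = c("uniform", "clustered",
                                            "gradient"),
                             pCtcf = 0.7, binSize = 10000,
                             nParalogFamilies = 4, familySize = 3,
                             tandemFraction = 0.5,
                             nSamples = 6, rhoTad = 0.3,
                             rhoTadCtcfOnly = FALSE,
                             decayWeight = 0.2, decayScale = 5e5,
                             floorFraction = 0.1, sdLog = 1.2,
                             annotationShare = 0.3,
                             backgroundShare = 0.05,
                             unannotatedFraction = 0.1,
                             constraintMean = 0, constraintSd = 1,
                             singletonShift = 0.5,
                             pseudoOlfactory = FALSE, seed = 1) {
  cfg <- list(nChromosomes = nChromosomes,
              chromosomeLength = chromosomeLength,
              nGenesPerChromosome = nGenesPerChromosome,
              geneLengthRange = geneLengthRange,
              tadStyle = match.arg(tadStyle),
              tadLengthRange = tadLengthRange,
              tadGapRange = tadGapRange, nestingRate = nestingRate,
              geneLayout = match.arg(geneLayout),
              pCtcf = pCtcf, binSize = binSize,
              nParalogFamilies = nParalogFamilies,
              familySize = familySize, tandemFraction = tandemFraction,
              nSamples = nSamples, rhoTad = rhoTad,
              rhoTadCtcfOnly = rhoTadCtcfOnly,
              decayWeight = decayWeight, decayScale = decayScale,
              floorFraction = floorFraction, sdLog = sdLog,
              annotationShare = annotationShare,
              backgroundShare = backgroundShare,
              unannotatedFraction = unannotatedFraction,
              constraintMean = constraintMean,
              constraintSd = constraintSd,
              singletonShift = singletonShift,
              pseudoOlfactory = pseudoOlfactory, seed = seed)
  probs <- c(cfg$nestingRate, cfg$pCtcf, cfg$tandemFraction,
             cfg$annotationShare, cfg$backgroundShare,
             cfg$unannotatedFraction, cfg$floorFraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$rhoTad < 0 || cfg$decayWeight < 0 ||
      cfg$rhoTad + cfg$decayWeight > 1)
    stop("rhoTad + decayWeight must lie in [0, 1]")
  structure(cfg, class = "SimulationConfig")
}

# Tile one chromosome with alternating gap/TAD blocks.
.tileTads <- function(L, lenRange, gapRange) {
  pos <- 0
  s <- numeric(); e <- numeric()
  repeat {
    gap <- round(stats::runif(1, gapRange[1], gapRange[2]))
    len <- round(stats::runif(1, lenRange[1], lenRange[2]))
    if (pos + gap + len > L) break
    s <- c(s, pos + gap)
    e <- c(e, pos + gap + len)
    pos <- pos + gap + len
  }
  data.frame(start0 = s, end0 = e)   # 0-based half-open
}

# Non-overlapping gene placement under a start-position sampler.
.placeGenes <- function(L, n, lenRange, sampleStart) {
  starts <- numeric(0); ends <- numeric(0)
  guard <- 0L
  while (length(starts) < n) {
    guard <- guard + 1L
    if (guard > 50000L)
      stop("gene placement failed: chromosome too crowded for the requested genes")
    len <- round(stats::runif(1, lenRange[1], lenRange[2]))
    s <- sampleStart(L - len)
    e <- s + len
    if (!length(starts) || all(e <= starts | s >= ends)) {
      starts <- c(starts, s); ends <- c(ends, e)
    }
  }
  ord <- order(starts)
  data.frame(start0 = starts[ord], end0 = ends[ord])
}

#' Simulate a genome with TADs, CTCF peaks and compartments
#'
#' @param cfg A \code{\link{simulationConfig}}. The generator is seeded by
#'   callers (see \code{\link{simulateAll}}); called directly it uses the
#'   current RNG state.
#' @return list(genome, tads, peaks, compartments).
#' @export
simulateGenome <- function(cfg) {
  L <- cfg$chromosomeLength
  if (cfg$nGenesPerChromosome * cfg$geneLengthRange[2] > 0.6 * L)
    stop(sprintf(
      "infeasible packing: %d genes x max length %g exceed 60%% of chromosome length %g",
      cfg$nGenesPerChromosome, cfg$geneLengthRange[2], L))
  chroms <- sprintf("chr%d", seq_len(cfg$nChromosomes))
  sizes <- setNames(rep(L, cfg$nChromosomes), chroms)
  geneRows <- list(); tadRows <- list(); peakRows <- list()
  compRows <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    tl <- .tileTads(L, cfg$tadLengthRange, cfg$tadGapRange)
    nested <- NULL
    if (cfg$tadStyle == "overlapping" && nrow(tl)) {
      pick <- which(stats::runif(nrow(tl)) < cfg$nestingRate)
      if (length(pick)) {
        w <- tl$end0[pick] - tl$start0[pick]
        nlen <- round(w * stats::runif(length(pick), 0.4, 0.7))
        noff <- round((w - nlen) * stats::runif(length(pick)))
        nested <- data.frame(start0 = tl$start0[pick] + noff,
                             end0 = tl$start0[pick] + noff + nlen)
      }
    }
    # gene placement
    if (cfg$geneLayout == "uniform") {
      gdf <- .placeGenes(L, cfg$nGenesPerChromosome, cfg$geneLengthRange,
                         function(mx) round(stats::runif(1, 0, mx)))
    } else if (cfg$geneLayout == "gradient") {
      gdf <- .placeGenes(L, cfg$nGenesPerChromosome, cfg$geneLengthRange,
                         function(mx) {
                           u <- stats::runif(1)
                           # density proportional to exp(-3 x / L)
                           round(-mx / 3 * log(1 - u * (1 - exp(-3))))
                         })
    } else {                           # clustered: tandem runs inside TADs
      starts <- numeric(); ends <- numeric()
      host <- sample(seq_len(nrow(tl)))
      hi <- 1L
      while (length(starts) < cfg$nGenesPerChromosome) {
        if (hi > length(host))
          stop("gene placement failed: not enough TADs to host gene clusters")
        t <- tl[host[hi], ]; hi <- hi + 1L
        k <- sample(2:6, 1)
        k <- min(k, cfg$nGenesPerChromosome - length(starts))
        margin <- 0.1 * (t$end0 - t$start0)
        pos <- t$start0 + margin
        for (j in seq_len(k)) {
          len <- round(stats::runif(1, cfg$geneLengthRange[1],
                                    cfg$geneLengthRange[2]))
          if (pos + len > t$end0 - margin) break
          starts <- c(starts, pos); ends <- c(ends, pos + len)
          # larger families are denser (tandem arrays), small ones looser
          pos <- pos + len + round(stats::runif(1, 400, 1200) * 2^(6 - k))
        }
      }
      gdf <- data.frame(start0 = starts, end0 = ends)
      gdf <- gdf[order(gdf$start0), ]
    }
    gdf$gene_id <- sprintf("g%04d", gid + seq_len(nrow(gdf)))
    gid <- gid + nrow(gdf)
    gdf$chrom <- chroms[ci]
    geneRows[[ci]] <- gdf
    allT <- rbind(tl, nested)
    allT$chrom <- chroms[ci]
    tadRows[[ci]] <- allT
    # CTCF peaks near boundaries, independently per boundary
    bounds <- c(allT$start0, allT$end0)
    hit <- stats::runif(length(bounds)) < cfg$pCtcf
    if (any(hit)) {
      ctr <- bounds[hit] +
        round(stats::runif(sum(hit), -(cfg$binSize - 500),
                           cfg$binSize - 500))
      ctr <- pmin(pmax(ctr, 150), L - 150)
      peakRows[[ci]] <- data.frame(chrom = chroms[ci],
                                   start0 = ctr - 150,
                                   end0 = ctr + 150)
    }
    # alternating A/B compartment blocks
    pos <- 0; cs <- numeric(); ce <- numeric()
    while (pos < L) {
      blk <- round(stats::runif(1, 1e5, 2e5))
      cs <- c(cs, pos); ce <- c(ce, min(L, pos + blk))
      pos <- pos + blk
    }
    compRows[[ci]] <- data.frame(chrom = chroms[ci], start0 = cs,
                                 end0 = ce,
                                 label = rep_len(c("A", "B"), length(cs)))
  }
  gdf <- do.call(rbind, geneRows)
  genome <- GenomeModel(data.frame(gene_id = gdf$gene_id,
                                   chrom = gdf$chrom,
                                   start = gdf$start0 + 1,
                                   end = gdf$end0), sizes)
  tdf <- do.call(rbind, tadRows)
  tads <- TADSet(data.frame(chrom = tdf$chrom, start = tdf$start0 + 1,
                            end = tdf$end0),
                 style = cfg$tadStyle, binSize = cfg$binSize)
  peaks <- if (length(peakRows)) {
    p <- do.call(rbind, peakRows)
    GRanges(p$chrom, IRanges(p$start0 + 1, p$end0))
  } else GRanges()
  cdf <- do.call(rbind, compRows)
  comp <- GRanges(cdf$chrom, IRanges(cdf$start0 + 1, cdf$end0))
  comp$compartment <- cdf$label
  list(genome = genome, tads = tads, peaks = peaks, compartments = comp)
}

#' Simulate paralog families
#'
#' Tandem families occupy consecutive genes inside one TAD; dispersed
#' families sample genes across the genome. Every within-family unordered
#' pair is emitted.
#'
#' @param cfg A \code{\link{simulationConfig}}.
#' @param genome A \code{GenomeModel}.
#' @param x The real \code{TADSet}.
#' @return list(pairs = data.frame(gene_a, gene_b), familyGenes).
#' @export
simulateParalogs <- function(cfg, genome, x) {
  k <- cfg$familySize
  nFam <- cfg$nParalogFamilies
  if (nFam * k > length(genes(genome)$gene_id))
    stop("paralog families exceed the number of available genes")
  map <- assignGenes(x, genome)
  nTandem <- round(cfg$tandemFraction * nFam)
  used <- character()
  fams <- list()
  hosts <- names(map$byTad)[vapply(map$byTad, length, integer(1)) >= k]
  hosts <- sample(hosts)
  nDemoted <- 0L
  for (f in seq_len(nTandem)) {
    hosts <- hosts[vapply(map$byTad[hosts], function(g)
      sum(!(g %in% used)) >= k, logical(1))]
    if (!length(hosts)) {
      # no TAD can host this tandem family; fall back to dispersed
      nDemoted <- nDemoted + (nTandem - f + 1L)
      break
    }
    h <- hosts[1L]; hosts <- hosts[-1L]
    g <- setdiff(map$byTad[[h]], used)
    i <- sample.int(length(g) - k + 1L, 1L)
    fams[[length(fams) + 1L]] <- g[i:(i + k - 1L)]
    used <- c(used, fams[[length(fams)]])
  }
  if (nDemoted)
    warning(sprintf(
      "%d tandem famil(y/ies) demoted to dispersed: no TAD holds %d unused genes",
      nDemoted, k))
  nTandem <- nTandem - nDemoted
  pool <- setdiff(genes(genome)$gene_id, used)
  for (f in seq_len(nFam - nTandem)) {
    pick <- sample(pool, k)
    fams[[length(fams) + 1L]] <- pick
    pool <- setdiff(pool, pick)
  }
  pairs <- do.call(rbind, lapply(fams, function(g) {
    cb <- utils::combn(sort(g), 2L)
    data.frame(gene_a = cb[1L, ], gene_b = cb[2L, ],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs))
    pairs <- data.frame(gene_a = character(), gene_b = character())
  list(pairs = pairs, familyGenes = fams)
}

#' Simulate an FPKM expression matrix with planted structure
#'
#' Latent per-gene profiles are a variance-weighted sum of a shared
#' per-TAD factor, a distance-decaying (AR-1 along the chromosome)
#' factor, and white noise; the Gaussian latent is pushed through a
#' monotone log-normal transform so Spearman targets survive the FPKM<1
#' flooring applied at analysis time.
#'
#' @param cfg A \code{\link{simulationConfig}}.
#' @param genome A \code{GenomeModel}.
#' @param x The real \code{TADSet}.
#' @param ctcfClass Optional data.frame from \code{\link{classifyCtcf}};
#'   with \code{cfg$rhoTadCtcfOnly} the TAD factor applies only in TADs
#'   labelled CTCF.
#' @return Gene x sample FPKM matrix.
#' @export
simulateExpression <- function(cfg, genome, x, ctcfClass = NULL) {
  if (cfg$nSamples < 4) stop("at least 4 expression samples required")
  g <- genes(genome)
  n <- length(g)
  map <- assignGenes(x, genome)
  tadOf <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tt <- map$byGene[[g$gene_id[i]]]
    if (!is.null(tt)) tadOf[i] <- tt[1L]
  }
  if (cfg$rhoTadCtcfOnly && !is.null(ctcfClass)) {
    ctcfTads <- ctcfClass$tad_id[ctcfClass$ctcf_class == "CTCF"]
    tadOf[!(tadOf %in% ctcfTads)] <- NA_character_
  }
  ns <- cfg$nSamples
  wT <- sqrt(cfg$rhoTad); wD <- sqrt(cfg$decayWeight)
  wE <- sqrt(1 - cfg$rhoTad - cfg$decayWeight)
  tadIds <- unique(stats::na.omit(tadOf))
  fTad <- matrix(stats::rnorm(length(tadIds) * ns), ncol = ns,
                 dimnames = list(tadIds, NULL))
  lat <- matrix(0, n, ns)
  # distance-decaying factor: AR(1) over genes ordered by position
  chr <- as.character(seqnames(g))
  u <- matrix(0, n, ns)
  for (c in unique(chr)) {
    i <- which(chr == c)          # genes are sorted by start already
    u[i[1L], ] <- stats::rnorm(ns)
    if (length(i) > 1L) for (j in 2:length(i)) {
      dgap <- start(g)[i[j]] - start(g)[i[j - 1L]]
      phi <- if (cfg$decayScale > 0) exp(-dgap / cfg$decayScale) else 0
      u[i[j], ] <- phi * u[i[j - 1L], ] +
        sqrt(1 - phi^2) * stats::rnorm(ns)
    }
  }
  for (i in seq_len(n)) {
    f <- if (!is.na(tadOf[i])) fTad[tadOf[i], ] else stats::rnorm(ns)
    lat[i, ] <- wT * f + wD * u[i, ] + wE * stats::rnorm(ns)
  }
  muLog <- -stats::qnorm(cfg$floorFraction) * cfg$sdLog
  fpkm <- exp(cfg$sdLog * lat + muLog)
  rownames(fpkm) <- g$gene_id
  colnames(fpkm) <- sprintf("s%02d", seq_len(ns))
  fpkm
}

#' Simulate GO, pathway and PPI annotations with planted sharing
#'
#' A two-level toy ontology (one root, intermediate terms, leaf terms) is
#' built with the leaf-pool size set to 1/backgroundShare, so the chance
#' collision of two random genes' own annotations realises exactly the
#' background sharing probability. Within-TAD sharing is planted via a
#' per-TAD leaf and a fresh per-TAD pathway given to each member gene
#' with probability q, with q^2 compounding with the background to the
#' target \code{annotationShare}; PPI edges are planted per pair. A
#' fraction of genes stays unannotated to exercise the NA paths.
#'
#' @param cfg A \code{\link{simulationConfig}}.
#' @param genome A \code{GenomeModel}.
#' @param x The real \code{TADSet}.
#' @return list(goAnnotations, ontologyEdges, pathways, ppiEdges).
#' @export
simulateAnnotations <- function(cfg, genome, x) {
  ids <- genes(genome)$gene_id
  bg <- cfg$backgroundShare
  s <- cfg$annotationShare
  # base vocabulary sized so that the chance collision of two random
  # genes' own annotations realises exactly the background sharing
  # probability (unique annotations when the background is zero)
  nLeaves <- if (bg > 0) max(8L, round(1 / bg)) else
    max(8L, length(ids))
  nMids <- max(2L, ceiling(nLeaves / 4))
  mids <- sprintf("M%02d", seq_len(nMids))
  leaves <- sprintf("L%03d", seq_len(nLeaves))
  edges <- rbind(data.frame(child = mids, parent = "R",
                            stringsAsFactors = FALSE),
                 data.frame(child = leaves,
                            parent = mids[((seq_len(nLeaves) - 1L) %%
                                           nMids) + 1L],
                            stringsAsFactors = FALSE))
  nUn <- round(cfg$unannotatedFraction * length(ids))
  unann <- if (nUn) sample(ids, nUn) else character()
  ann <- setdiff(ids, unann)
  go <- setNames(vector("list", length(ann)), ann)
  pw <- setNames(vector("list", length(ann)), ann)
  nPw <- if (bg > 0) max(4L, round(1 / bg)) else max(4L, length(ids))
  pwPool <- sprintf("P%03d", seq_len(nPw))
  for (g in ann) {
    go[[g]] <- if (bg > 0) sample(leaves, 1) else
      leaves[match(g, ids)]
    pw[[g]] <- if (bg > 0) sample(pwPool, 1) else
      pwPool[match(g, ids)]
  }
  # within-TAD sharing: each TAD draws a leaf and a fresh pathway; each
  # member gene receives them with probability q, chosen so that q^2
  # compounds with the background collisions to the target share
  q <- if (s <= bg) 0 else sqrt((s - bg) / (1 - bg))
  if (q > 0) {
    map <- assignGenes(x, genome)
    for (t in names(map$byTad)) {
      gs <- intersect(map$byTad[[t]], ann)
      if (length(gs) < 2L) next
      tadLeaf <- sample(leaves, 1)
      tadPw <- sprintf("PT_%s", t)
      take <- gs[stats::runif(length(gs)) < q]
      for (g in take) go[[g]] <- unique(c(go[[g]], tadLeaf))
      take <- gs[stats::runif(length(gs)) < q]
      for (g in take) pw[[g]] <- unique(c(pw[[g]], tadPw))
    }
  }
  # PPI edges are pair-specific: planted directly per pair
  tadPairs <- enumerateTadPairs(x, genome)
  tadKeys <- .pairKey(tadPairs$gene_a, tadPairs$gene_b)
  cb <- utils::combn(sort(ids), 2L)   # incl. cross-chromosome pairs
  bgAll <- data.frame(gene_a = cb[1L, ], gene_b = cb[2L, ],
                      stringsAsFactors = FALSE)
  isTad <- .pairKey(bgAll$gene_a, bgAll$gene_b) %in% tadKeys
  share <- ifelse(isTad, s, bg)
  hit <- stats::runif(nrow(bgAll)) < share
  ppi <- unique(data.frame(gene_a = bgAll$gene_a[hit],
                           gene_b = bgAll$gene_b[hit],
                           stringsAsFactors = FALSE))
  list(goAnnotations = go, ontologyEdges = edges, pathways = pw,
       ppiEdges = ppi)
}

#' Simulate per-transcript constraint scores with a singleton shift
#'
#' Transcript scores are Normal(background mean, sd); every gene that
#' singly occupies some TAD receives an additional shift. Genes carry one
#' to three transcripts.
#'
#' @param cfg A \code{\link{simulationConfig}}.
#' @param genome A \code{GenomeModel}.
#' @param x The real \code{TADSet}.
#' @return data.frame(transcript_id, gene_id, score).
#' @export
simulateConstraint <- function(cfg, genome, x) {
  ids <- genes(genome)$gene_id
  counts <- geneCounts(x, genome)
  map <- assignGenes(x, genome)
  singletonTads <- tads(x)$tad_id[counts == 1L]
  singletons <- unique(unlist(map$byTad[singletonTads]))
  rows <- lapply(ids, function(g) {
    nt <- sample(1:3, 1)
    sc <- stats::rnorm(nt, cfg$constraintMean, cfg$constraintSd) +
      if (g %in% singletons) cfg$singletonShift else 0
    data.frame(transcript_id = sprintf("%s_t%d", g, seq_len(nt)),
               gene_id = g, score = sc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a complete synthetic dataset
#'
#' One seed reproduces every output exactly; every generated object
#' passes the package validators.
#'
#' @param cfg A \code{\link{simulationConfig}}.
#' @return list(genome, tads, peaks, compartments, expression, corpus,
#'   config) where corpus is an \code{AnnotationCorpus} bundling the
#'   simulated paralogs, GO/pathway/PPI annotations, constraint table and
#'   (optionally) the pseudo-olfactory mask.
#' @export
simulateAll <- function(cfg) {
  .withSeed(cfg$seed, function() {
    base <- simulateGenome(cfg)
    mask <- character()
    paralogs <- simulateParalogs(cfg, base$genome, base$tads)
    if (cfg$pseudoOlfactory) {
      map <- assignGenes(base$tads, base$genome)
      sizes <- vapply(map$byTad, length, integer(1))
      host <- names(sizes)[which.max(sizes)]
      mask <- map$byTad[[host]]
    }
    ctcf <- classifyCtcf(base$tads, base$peaks, windowBp = cfg$binSize)
    expr <- simulateExpression(cfg, base$genome, base$tads, ctcf)
    anns <- simulateAnnotations(cfg, base$genome, base$tads)
    cons <- simulateConstraint(cfg, base$genome, base$tads)
    corpus <- AnnotationCorpus(goAnnotations = anns$goAnnotations,
                               ontologyEdges = anns$ontologyEdges,
                               pathways = anns$pathways,
                               ppiEdges = anns$ppiEdges,
                               paralogPairs = paralogs$pairs,
                               maskGenes = mask, constraint = cons)
    list(genome = base$genome, tads = base$tads, peaks = base$peaks,
         compartments = base$compartments, expression = expr,
         corpus = corpus, config = cfg)
  })
}
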