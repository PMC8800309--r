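# Gene-to-TAD assignment (strict containment), boundary CTCF
# classification, compartment assignment, occupancy classes, constraint
# aggregation and caller concordance.

#' Strict-containment gene counts per TAD
#'
#' @param x A \code{TADSet}.
#' @param genome A \code{GenomeModel}.
#' @return Integer vector, one count per TAD (in \code{tads(x)} order): the
#'   number of genes whose start AND end fall within the TAD.
#' @export
geneCounts <- function(x, genome) {
  gr <- tads(x)
  g <- genes(genome)
  if (!length(gr)) return(integer())
  if (!length(g)) return(integer(length(gr)))
  gchr <- as.character(seqnames(g)); gs <- start(g); ge <- end(g)
  tchr <- as.character(seqnames(gr)); ts <- start(gr); te <- end(gr)
  chrIdx <- split(seq_along(gs), gchr)
  vapply(seq_along(ts), function(k) {
    i <- chrIdx[[tchr[k]]]
    if (is.null(i)) return(0L)
    sum(gs[i] >= ts[k] & ge[i] <= te[k])
  }, integer(1))
}

#' Assign genes to TADs under the strict containment rule
#'
#' A gene belongs to a TAD iff both its start and end coordinate fall
#' within that TAD; genes straddling a boundary belong to no TAD. With
#' nested or overlapping TADs a gene may belong to several TADs.
#'
#' @param x A \code{TADSet}.
#' @param genome A \code{GenomeModel}.
#' @return A list of class "TADGeneMap" with elements \code{byTad} (named
#'   list: tad_id -> gene ids, sorted by gene start) and \code{byGene}
#'   (named list: gene_id -> tad ids).
#' @export
assignGenes <- function(x, genome) {
  gr <- tads(x)
  g <- genes(genome)
  byTad <- setNames(vector("list", length(gr)), gr$tad_id)
  byTad[] <- list(character())
  byGene <- list()
  if (length(gr) && length(g)) {
    gchr <- as.character(seqnames(g)); gs <- start(g); ge <- end(g)
    gid <- g$gene_id                  # genes are sorted by (chrom, start)
    tchr <- as.character(seqnames(gr)); ts <- start(gr); te <- end(gr)
    chrIdx <- split(seq_along(gs), gchr)
    hitG <- integer(0); hitT <- integer(0)
    for (k in seq_along(ts)) {
      i <- chrIdx[[tchr[k]]]
      if (is.null(i)) next
      j <- i[gs[i] >= ts[k] & ge[i] <= te[k]]
      if (length(j)) {
        byTad[[k]] <- gid[j]
        hitG <- c(hitG, j); hitT <- c(hitT, rep.int(k, length(j)))
      }
    }
    if (length(hitG)) byGene <- split(gr$tad_id[hitT], gid[hitG])
  }
  structure(list(byTad = byTad, byGene = byGene), class = "TADGeneMap")
}

#' Classify TADs by CTCF peak support at their boundaries
#'
#' A boundary is supported when some peak interval intersects the window
#' boundary +/- \code{windowBp} (default one 10 kb Hi-C bin). TADs with
#' both boundaries supported are "CTCF"; one or zero supported boundaries
#' give "nonCTCF_one" / "nonCTCF_zero" (jointly the nonCTCF class).
#'
#' @param x A \code{TADSet}.
#' @param peaks A \code{GRanges} of ChIP-seq peak intervals.
#' @param windowBp Window half-width in bp (default 10000). With 0 only
#'   peaks covering the exact boundary coordinate count.
#' @return data.frame(tad_id, ctcf_class).
#' @export
classifyCtcf <- function(x, peaks, windowBp = 10000) {
  stopifnot(windowBp >= 0)
  gr <- tads(x)
  # 0-based boundary coordinates; peaks as 0-based half-open intervals
  bl <- start(gr) - 1
  br <- end(gr)
  chr <- as.character(seqnames(gr))
  ps0 <- start(peaks) - 1
  pe0 <- end(peaks)
  pchr <- as.character(seqnames(peaks))
  supported <- function(b, c) {
    i <- pchr == c
    if (!any(i)) return(rep(FALSE, length(b)))
    s <- ps0[i]; e <- pe0[i]
    vapply(b, function(bb) any(s <= bb + windowBp & e > bb - windowBp),
           logical(1))
  }
  supL <- logical(length(gr)); supR <- logical(length(gr))
  for (c in unique(chr)) {
    j <- chr == c
    supL[j] <- supported(bl[j], c)
    supR[j] <- supported(br[j], c)
  }
  cls <- ifelse(supL & supR, "CTCF",
                ifelse(supL | supR, "nonCTCF_one", "nonCTCF_zero"))
  data.frame(tad_id = gr$tad_id, ctcf_class = cls,
             stringsAsFactors = FALSE)
}

#' Assign TADs to A/B compartments by majority base-pair overlap
#'
#' Each TAD is labelled with the compartment covering the larger share of
#' its bases; an exact tie or zero overlap gives "unassigned".
#'
#' @param x A \code{TADSet}.
#' @param track A \code{GRanges} with a \code{compartment} column ("A"/"B").
#' @return data.frame(tad_id, compartment).
#' @export
assignCompartment <- function(x, track) {
  gr <- tads(x)
  out <- rep("unassigned", length(gr))
  if (length(gr) && length(track)) {
    tt <- GRanges(as.character(seqnames(gr)), IRanges(start(gr), end(gr)))
    cov <- matrix(0, nrow = length(gr), ncol = 2,
                  dimnames = list(NULL, c("A", "B")))
    hits <- findOverlaps(tt, track)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      w <- width(pintersect(tt[qh], track[sh]))
      lab <- track$compartment[sh]
      for (l in c("A", "B")) {
        i <- lab == l
        if (any(i)) {
          agg <- tapply(w[i], qh[i], sum)
          cov[as.integer(names(agg)), l] <- agg
        }
      }
      out[cov[, "A"] > cov[, "B"]] <- "A"
      out[cov[, "B"] > cov[, "A"]] <- "B"
    }
  }
  data.frame(tad_id = gr$tad_id, compartment = out,
             stringsAsFactors = FALSE)
}

#' Occupancy classes (1, 2, 3, 4, 5, 6+) from gene counts
#'
#' Zero-gene TADs are excluded from occupancy analyses (class NA) and their
#' number reported via message().
#'
#' @param counts Integer vector of per-TAD gene counts (from
#'   \code{geneCounts}), optionally named by tad id.
#' @return Factor with levels "1".."5", "6+"; NA for zero-gene TADs.
#' @export
occupancyClasses <- function(counts) {
  nZero <- sum(counts == 0L)
  if (nZero)
    message(sprintf("occupancyClasses: %d zero-gene TAD(s) excluded", nZero))
  lv <- c("1", "2", "3", "4", "5", "6+")
  cls <- ifelse(counts == 0L, NA_character_,
                ifelse(counts >= 6L, "6+", as.character(counts)))
  factor(cls, levels = lv)
}

#' Within-TAD intergene start-to-start distances
#'
#' Pools, over the deduplicated within-TAD gene pairs (see
#' \code{\link{enumerateTadPairs}}), the absolute differences between gene
#' start coordinates.
#'
#' @param x A \code{TADSet}.
#' @param genome A \code{GenomeModel}.
#' @return Numeric vector of bp distances, one per deduplicated pair.
#' @export
intergeneDistances <- function(x, genome) {
  pairs <- enumerateTadPairs(x, genome)
  pairs$distance
}

#' Mean constraint score of genes sharing a TAD
#'
#' Pools the nonsynonymous z-scores of ALL transcripts of all contained
#' genes and takes the arithmetic mean per TAD (per-transcript pooling; a
#' per-gene-mean variant is available). TADs whose genes carry no
#' constraint score are excluded and counted.
#'
#' @param x A \code{TADSet}.
#' @param genome A \code{GenomeModel}.
#' @param corpus An \code{AnnotationCorpus} with a constraint table.
#' @param perGeneMean If TRUE, average each gene's transcripts first.
#' @return data.frame(tad_id, n_genes, n_scored_genes, mean_constraint)
#'   restricted to TADs with at least one scored gene; the number excluded
#'   is in \code{attr(result, "n_excluded")}.
#' @export
meanConstraint <- function(x, genome, corpus, perGeneMean = FALSE) {
  map <- assignGenes(x, genome)
  cons <- corpus@constraint
  scoresByGene <- split(cons$score, cons$gene_id)
  geneSum <- vapply(scoresByGene,
                    if (perGeneMean) mean else sum, numeric(1))
  geneN <- if (perGeneMean) rep(1, length(scoresByGene))
           else vapply(scoresByGene, function(s) as.numeric(length(s)),
                       numeric(1))
  names(geneN) <- names(scoresByGene)
  counts <- geneCounts(x, genome)
  tid <- tads(x)$tad_id
  nTad <- vapply(map$byTad, length, integer(1))
  flatGene <- unlist(map$byTad, use.names = FALSE)
  flatTad <- rep(seq_along(tid), nTad[tid])
  scored <- flatGene %in% names(geneSum)
  agg <- function(v) {
    out <- numeric(length(tid))
    if (any(scored)) {
      a <- rowsum(v[flatGene[scored]], flatTad[scored])
      out[as.integer(rownames(a))] <- a
    }
    out
  }
  sumS <- agg(geneSum)
  sumN <- agg(geneN)
  nScored <- integer(length(tid))
  if (any(scored)) {
    a <- rowsum(rep(1L, sum(scored)), flatTad[scored])
    nScored[as.integer(rownames(a))] <- a
  }
  out <- data.frame(tad_id = tid, n_genes = counts,
                    n_scored_genes = nScored,
                    mean_constraint = ifelse(sumN > 0, sumS / sumN,
                                             NA_real_),
                    stringsAsFactors = FALSE)
  nExcluded <- sum(is.na(out$mean_constraint))
  out <- out[!is.na(out$mean_constraint), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- nExcluded
  out
}

#' Boundary concordance between two TAD callers
#'
#' A TAD in one set is concordant when the other set has a TAD whose start
#' and end both lie within \code{toleranceBins * binSize} bp.
#'
#' @param a,b \code{TADSet}s on the same assembly.
#' @param toleranceBins Tolerance in bins (default 2).
#' @param binSize Bin size in bp (default 10000).
#' @return list(a_in_b, b_in_a): the fraction of each set with an
#'   equivalent TAD in the other.
#' @export
callerConcordance <- function(a, b, toleranceBins = 2, binSize = 10000) {
  tol <- toleranceBins * binSize
  frac <- function(x, y) {
    gx <- tads(x); gy <- tads(y)
    if (!length(gx)) return(NA_real_)
    if (!length(gy)) return(0)
    chrX <- as.character(seqnames(gx)); chrY <- as.character(seqnames(gy))
    hit <- vapply(seq_along(gx), function(i) {
      j <- chrY == chrX[i]
      any(abs(start(gy)[j] - start(gx)[i]) <= tol &
          abs(end(gy)[j] - end(gx)[i]) <= tol)
    }, logical(1))
    mean(hit)
  }
  list(a_in_b = frac(a, b), b_in_a = frac(b, a))
}

#' One-row-per-TAD annotation table
#'
#' Convenience combining gene counts, occupancy class, CTCF class,
#' compartment and mean constraint into a single table.
#'
#' @param x A \code{TADSet}.
#' @param genome A \code{GenomeModel}.
#' @param peaks Optional peak \code{GRanges} for CTCF classification.
#' @param track Optional compartment \code{GRanges}.
#' @param corpus Optional \code{AnnotationCorpus} for constraint scores.
#' @param windowBp CTCF boundary window (default 10000).
#' @return data.frame with one row per TAD.
#' @export
annotateTads <- function(x, genome, peaks = NULL, track = NULL,
                         corpus = NULL, windowBp = 10000) {
  gr <- tads(x)
  counts <- geneCounts(x, genome)
  out <- data.frame(tad_id = gr$tad_id,
                    chrom = as.character(seqnames(gr)),
                    start = start(gr) - 1, end = end(gr),
                    n_genes = counts,
                    occupancy_class = as.character(
                      suppressMessages(occupancyClasses(counts))),
                    stringsAsFactors = FALSE)
  if (!is.null(peaks))
    out$ctcf_class <- classifyCtcf(x, peaks, windowBp)$ctcf_class
  if (!is.null(track))
    out$compartment <- assignCompartment(x, track)$compartment
  if (!is.null(corpus)) {
    mc <- meanConstraint(x, genome, corpus)
    out$mean_constraint <- mc$mean_constraint[match(out$tad_id, mc$tad_id)]
  }
  out
}
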