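# Deduplicated within-TAD gene pairs and all per-pair similarity metrics:
# paralogy, rank-correlation of expression, GO semantic similarity (Jiang
# measure, best-match-average combination), shared pathways and PPIs, plus
# genome-wide distance-binned pair summaries with gene-identity
# permutation testing.

.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

.orderPair <- function(df) {
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]
  df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp
  df
}

#' Enumerate deduplicated within-TAD gene pairs
#'
#' Takes the union over TADs of each TAD's unordered within-TAD gene
#' pairs, collapsing duplicates. This realises the nested/overlap
#' deduplication rules: nested TADs contribute the enclosing TAD's pairs
#' once, and pairs from a region shared by partially overlapping TADs
#' appear once.
#'
#' @param x A \code{TADSet}.
#' @param genome A \code{GenomeModel}.
#' @return data.frame(gene_a, gene_b, distance) with gene_a < gene_b and
#'   distance the absolute difference of gene start coordinates (bp).
#' @export
enumerateTadPairs <- function(x, genome) {
  map <- assignGenes(x, genome)
  g <- genes(genome)
  starts <- setNames(start(g) - 1, g$gene_id)   # 0-based starts
  .pairsFromMap(map, starts)
}

# Union of within-TAD unordered pairs from an existing TADGeneMap,
# optionally restricted to a subset of TADs. starts: named 0-based gene
# start vector for the distance column.
.pairsFromMap <- function(map, starts, tadIds = NULL) {
  byTad <- map$byTad
  if (!is.null(tadIds)) byTad <- byTad[names(byTad) %in% tadIds]
  sizes <- lengths(byTad)
  byTad <- byTad[sizes >= 2L]
  if (!length(byTad))
    return(data.frame(gene_a = character(), gene_b = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  aList <- vector("list", length(byTad))
  bList <- vector("list", length(byTad))
  for (i in seq_along(byTad)) {
    cb <- utils::combn(byTad[[i]], 2L)
    aList[[i]] <- cb[1L, ]; bList[[i]] <- cb[2L, ]
  }
  a <- unlist(aList, use.names = FALSE)
  b <- unlist(bList, use.names = FALSE)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  keep <- !duplicated(paste(a, b, sep = "\r"))
  a <- a[keep]; b <- b[keep]
  out <- data.frame(gene_a = a, gene_b = b,
                    distance = abs(starts[a] - starts[b]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Enumerate all same-chromosome gene pairs genome-wide
#'
#' @param genome A \code{GenomeModel}.
#' @param mask Optional gene ids to exclude first.
#' @return data.frame(gene_a, gene_b, distance) over all unordered pairs
#'   of genes sharing a chromosome.
#' @export
allGenePairs <- function(genome, mask = NULL) {
  g <- genes(genome)
  if (!is.null(mask)) g <- g[!(g$gene_id %in% mask)]
  chr <- as.character(seqnames(g))
  starts <- start(g) - 1
  acc <- lapply(unique(chr), function(c) {
    i <- which(chr == c)
    if (length(i) < 2L) return(NULL)
    cb <- utils::combn(i, 2L)
    data.frame(gene_a = g$gene_id[cb[1L, ]], gene_b = g$gene_id[cb[2L, ]],
               distance = abs(starts[cb[1L, ]] - starts[cb[2L, ]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, acc)
  if (is.null(out))
    return(data.frame(gene_a = character(), gene_b = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  out <- .orderPair(out)
  rownames(out) <- NULL
  out
}

#' Flag paralogous pairs in a gene-pair table
#'
#' @param pairs data.frame with gene_a / gene_b columns.
#' @param corpus An \code{AnnotationCorpus} with a paralog pair table.
#' @return The table with a logical \code{is_paralog} column.
#' @export
flagParalogs <- function(pairs, corpus) {
  pp <- corpus@paralogPairs
  keys <- if (nrow(pp)) .pairKey(pp$gene_a, pp$gene_b) else character()
  pairs$is_paralog <- .pairKey(pairs$gene_a, pairs$gene_b) %in% keys
  pairs
}

#' Remove paralogous pairs from a gene-pair table
#'
#' @inheritParams flagParalogs
#' @return The table without paralog pairs; the number removed is stored
#'   in \code{attr(result, "n_removed")}.
#' @export
filterParalogPairs <- function(pairs, corpus) {
  flagged <- flagParalogs(pairs, corpus)
  keep <- !flagged$is_paralog
  if (!any(keep) && nrow(pairs))
    warning("all pairs were paralogous; empty table returned")
  out <- pairs[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' 2x2 paralog enrichment counts (real vs null pairs)
#'
#' @param tadPairs,nullPairs Pair tables carrying \code{is_paralog} flags
#'   (see \code{\link{flagParalogs}}).
#' @return 2x2 integer matrix, rows real/null, columns paralog/other,
#'   suitable for \code{\link{fisherExact}}.
#' @export
paralogEnrichmentCounts <- function(tadPairs, nullPairs) {
  stopifnot(!is.null(tadPairs$is_paralog), !is.null(nullPairs$is_paralog))
  m <- matrix(c(sum(tadPairs$is_paralog), sum(!tadPairs$is_paralog),
                sum(nullPairs$is_paralog), sum(!nullPairs$is_paralog)),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("real", "null"), c("paralog", "other")))
  if (any(rowSums(m) == 0))
    stop("paralogEnrichmentCounts: a row with zero total")
  m
}

# Standardised (zero-mean, unit-norm) average-rank matrix of the floored
# expression values; constant rows are NA. The Spearman correlation of two
# genes is then the inner product of their rows.
.rankMatrix <- function(expr) {
  m <- expr
  m[m < 1] <- 0
  r <- t(apply(m, 1L, rank))
  ctr <- r - rowMeans(r)
  nrm <- sqrt(rowSums(ctr^2))
  z <- ctr / ifelse(nrm > 0, nrm, NA_real_)
  z
}

.spearmanFromRanks <- function(z, a, b) {
  ia <- match(a, rownames(z))
  ib <- match(b, rownames(z))
  out <- rep(NA_real_, length(a))
  ok <- !is.na(ia) & !is.na(ib)
  if (any(ok)) {
    v <- rowSums(z[ia[ok], , drop = FALSE] * z[ib[ok], , drop = FALSE])
    out[ok] <- pmin(1, pmax(-1, v))
  }
  out
}

#' Expression correlation for gene pairs (floored Spearman)
#'
#' Values below 1 FPKM are treated as 0 expression before computing
#' Spearman's rank correlation (average ranks for ties) across samples.
#' Pairs where either floored vector is constant, or where a gene is
#' absent from the matrix, get NA.
#'
#' @param pairs data.frame with gene_a / gene_b columns.
#' @param expr Gene x sample numeric matrix (at least 4 samples; the
#'   correlation analysis requires more than three).
#' @return The table with a \code{correlation} column in [-1, 1].
#' @export
coexpression <- function(pairs, expr) {
  if (ncol(expr) <= 3L)
    stop("coexpression requires more than three samples")
  z <- .rankMatrix(expr)
  pairs$correlation <- .spearmanFromRanks(z, pairs$gene_a, pairs$gene_b)
  nMissing <- sum(!(pairs$gene_a %in% rownames(expr)) |
                  !(pairs$gene_b %in% rownames(expr)))
  if (nMissing)
    message(sprintf("coexpression: %d pair(s) with gene(s) absent from the matrix -> NA",
                    nMissing))
  pairs
}

#' Build an information-content index over a GO ontology
#'
#' Computes, per term: the reflexive ancestor closure from the parent-edge
#' list, the corpus probability under the true-path rule (a gene annotated
#' to a term counts for every ancestor), the information content
#' IC = -ln p normalised to [0, 1] by the corpus maximum, and the full
#' pairwise Jiang similarity matrix.
#'
#' @param corpus An \code{AnnotationCorpus} with GO annotations and
#'   ontology edges.
#' @return An \code{OntologyIndex}.
#' @export
buildOntologyIndex <- function(corpus) {
  edges <- corpus@ontologyEdges
  anns <- corpus@goAnnotations
  terms <- unique(c(edges$child, edges$parent, unlist(anns,
                                                      use.names = FALSE)))
  if (!length(terms)) stop("no ontology terms found")
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  # Kahn topological order (parents before children); detects cycles
  nParents <- vapply(parents, length, integer(1))
  childrenOf <- split(edges$child, factor(edges$parent, levels = terms))
  roots <- terms[nParents == 0L]
  if (length(roots) != 1L)
    stop(sprintf("ontology must have exactly one root; found %d",
                 length(roots)))
  order <- character(0)
  pending <- nParents
  queue <- roots
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    order <- c(order, t)
    for (ch in childrenOf[[t]]) {
      pending[[ch]] <- pending[[ch]] - 1L
      if (pending[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != length(terms))
    stop("cycle detected in ontology edge list")
  ancestors <- setNames(vector("list", length(terms)), terms)
  for (t in order) {
    ancestors[[t]] <- unique(c(t, unlist(ancestors[parents[[t]]],
                                         use.names = FALSE)))
  }
  # true-path gene sets
  genesOf <- setNames(vector("list", length(terms)), terms)
  for (g in names(anns)) {
    tt <- intersect(unique(anns[[g]]), terms)
    up <- unique(unlist(ancestors[tt], use.names = FALSE))
    for (t in up) genesOf[[t]] <- c(genesOf[[t]], g)
  }
  nOf <- vapply(genesOf, function(v) length(unique(v)), integer(1))
  root <- roots
  if (nOf[[root]] == 0L) stop("no annotated genes reach the ontology root")
  p <- nOf / nOf[[root]]
  rawIC <- -log(p)
  if (any(!is.finite(rawIC))) {
    warning(sprintf("%d term(s) with zero corpus frequency are unusable",
                    sum(!is.finite(rawIC))))
  }
  mx <- max(rawIC[is.finite(rawIC)])
  ic <- if (mx > 0) rawIC / mx else rawIC
  ic[!is.finite(ic)] <- NA_real_
  usable <- terms[!is.na(ic)]
  sim <- matrix(NA_real_, length(usable), length(usable),
                dimnames = list(usable, usable))
  for (i in seq_along(usable)) {
    for (j in i:length(usable)) {
      t1 <- usable[i]; t2 <- usable[j]
      common <- intersect(ancestors[[t1]], ancestors[[t2]])
      common <- common[!is.na(ic[common])]
      if (!length(common)) next
      mica <- max(ic[common])
      d <- ic[[t1]] + ic[[t2]] - 2 * mica
      sim[i, j] <- sim[j, i] <- 1 - min(1, d)
    }
  }
  new("OntologyIndex", ic = ic, ancestors = ancestors, termSim = sim,
      root = root)
}

#' Jiang similarity between two ontology terms
#'
#' sim = 1 - min(1, IC(t1) + IC(t2) - 2 IC(MICA)) on normalised
#' information content, where MICA is the common ancestor (reflexively)
#' with maximal IC. Symmetric; 1 for identical terms.
#'
#' @param index An \code{OntologyIndex}.
#' @param term1,term2 Term ids with finite IC.
#' @return Similarity in [0, 1].
#' @export
jiangSimilarity <- function(index, term1, term2) {
  ic <- index@ic
  if (!term1 %in% names(ic) || !term2 %in% names(ic))
    stop("unknown ontology term")
  if (is.na(ic[[term1]]) || is.na(ic[[term2]]))
    stop("term with undefined information content")
  s <- index@termSim[term1, term2]
  if (is.na(s)) stop("terms share no common ancestor")
  unname(s)
}

#' Best-match-average GO similarity of a gene pair
#'
#' With term sets S1 (size n1) and S2 (size n2),
#' BMA = (sum over S1 of the best match in S2 + sum over S2 of the best
#' match in S1) / (n1 + n2). Genes with no usable annotated terms give NA
#' (such pairs are excluded downstream).
#'
#' @param index An \code{OntologyIndex}.
#' @param corpus An \code{AnnotationCorpus}.
#' @param geneA,geneB Gene ids.
#' @return Similarity in [0, 1], or NA.
#' @export
geneGoSimilarity <- function(index, corpus, geneA, geneB) {
  anns <- corpus@goAnnotations
  usable <- rownames(index@termSim)
  s1 <- intersect(unique(anns[[geneA]]), usable)
  s2 <- intersect(unique(anns[[geneB]]), usable)
  if (!length(s1) || !length(s2)) return(NA_real_)
  m <- index@termSim[s1, s2, drop = FALSE]
  (sum(apply(m, 1L, max)) + sum(apply(m, 2L, max))) /
    (length(s1) + length(s2))
}

#' GO similarity column for a gene-pair table
#'
#' @param pairs data.frame with gene_a / gene_b columns.
#' @param index An \code{OntologyIndex}.
#' @param corpus An \code{AnnotationCorpus}.
#' @return The table with a \code{go_sim} column (NA when either gene is
#'   unannotated).
#' @export
goSimilarity <- function(pairs, index, corpus) {
  pairs$go_sim <- vapply(seq_len(nrow(pairs)), function(i)
    geneGoSimilarity(index, corpus, pairs$gene_a[i], pairs$gene_b[i]),
    numeric(1))
  pairs
}

#' Shared-pathway flag for a gene-pair table
#'
#' TRUE iff the two genes' pathway sets intersect; NA when either gene has
#' no pathway annotation (the downstream proportion is over non-NA pairs
#' only, i.e. pairs with at least one annotation each).
#'
#' @param pairs data.frame with gene_a / gene_b columns.
#' @param corpus An \code{AnnotationCorpus}.
#' @return The table with a logical \code{shares_pathway} column.
#' @export
sharedPathway <- function(pairs, corpus) {
  pw <- corpus@pathways
  pairs$shares_pathway <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- pw[[pairs$gene_a[i]]]
    b <- pw[[pairs$gene_b[i]]]
    if (is.null(a) || is.null(b) || !length(a) || !length(b))
      return(NA)
    length(intersect(a, b)) > 0L
  }, logical(1))
  pairs
}

#' Shared-PPI flag for a gene-pair table
#'
#' Default semantics: TRUE iff the unordered pair itself is a physical
#' interaction edge. Alternative "partner" semantics: TRUE iff the two
#' genes share at least one interaction partner. Either way, NA when
#' either gene participates in no edge (proportions are over pairs with at
#' least one PPI annotation each).
#'
#' @param pairs data.frame with gene_a / gene_b columns.
#' @param corpus An \code{AnnotationCorpus}.
#' @param mode "direct" (default) or "partner".
#' @return The table with a logical \code{shares_ppi} column.
#' @export
sharedPpi <- function(pairs, corpus, mode = c("direct", "partner")) {
  mode <- match.arg(mode)
  ed <- corpus@ppiEdges
  nb <- split(c(ed$gene_b, ed$gene_a), c(ed$gene_a, ed$gene_b))
  keys <- if (nrow(ed)) .pairKey(ed$gene_a, ed$gene_b) else character()
  pairs$shares_ppi <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    na <- nb[[a]]; nbb <- nb[[b]]
    if (is.null(na) || is.null(nbb)) return(NA)
    if (mode == "direct") .pairKey(a, b) %in% keys
    else length(intersect(na, nbb)) > 0L
  }, logical(1))
  pairs
}

#' Attach every configured similarity metric to a pair table
#'
#' @param pairs data.frame with gene_a / gene_b columns.
#' @param expr Optional expression matrix (adds \code{correlation}).
#' @param corpus Optional \code{AnnotationCorpus} (adds \code{is_paralog},
#'   \code{shares_pathway}, \code{shares_ppi}).
#' @param index Optional \code{OntologyIndex} (adds \code{go_sim}).
#' @param ppiMode Passed to \code{\link{sharedPpi}}.
#' @return The pair table with metric columns; NAs are metric-by-metric.
#' @export
pairMetrics <- function(pairs, expr = NULL, corpus = NULL, index = NULL,
                        ppiMode = "direct") {
  if (!is.null(expr)) pairs <- suppressMessages(coexpression(pairs, expr))
  if (!is.null(corpus)) {
    pairs <- flagParalogs(pairs, corpus)
    pairs <- sharedPathway(pairs, corpus)
    pairs <- sharedPpi(pairs, corpus, mode = ppiMode)
    if (!is.null(index)) pairs <- goSimilarity(pairs, index, corpus)
  }
  pairs
}

#' Precompute gene-by-gene metric lookup matrices
#'
#' Computes every pairwise similarity metric once over the whole gene
#' universe, so that repeated pair-table evaluations (one per null set or
#' permuted genome) become constant-time lookups. Values agree exactly
#' with the per-pair functions.
#'
#' @param genome A \code{GenomeModel} (defines the gene universe).
#' @param expr Optional expression matrix.
#' @param corpus Optional \code{AnnotationCorpus}.
#' @param index Optional \code{OntologyIndex}.
#' @param ppiMode Passed semantics for \code{shares_ppi} ("direct" or
#'   "partner").
#' @return list(ids, correlation, go_sim, shares_pathway, shares_ppi,
#'   is_paralog); matrix entries are NA under the same rules as the
#'   per-pair metrics.
#' @export
pairMetricMatrices <- function(genome, expr = NULL, corpus = NULL,
                               index = NULL, ppiMode = "direct") {
  ids <- genes(genome)$gene_id
  n <- length(ids)
  out <- list(ids = ids)
  if (!is.null(expr)) {
    z <- .rankMatrix(expr)
    zi <- matrix(NA_real_, n, ncol(z))
    hit <- match(ids, rownames(z))
    ok <- !is.na(hit)
    zi[ok, ] <- z[hit[ok], , drop = FALSE]
    m <- zi %*% t(zi)
    m[m > 1] <- 1; m[m < -1] <- -1
    dimnames(m) <- list(ids, ids)
    out$correlation <- m
  }
  if (!is.null(corpus)) {
    P <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    pp <- corpus@paralogPairs
    if (nrow(pp)) {
      ia <- match(pp$gene_a, ids); ib <- match(pp$gene_b, ids)
      ok <- !is.na(ia) & !is.na(ib)
      P[cbind(ia[ok], ib[ok])] <- TRUE
      P[cbind(ib[ok], ia[ok])] <- TRUE
    }
    out$is_paralog <- P
    pw <- corpus@pathways
    pwIds <- unique(unlist(pw, use.names = FALSE))
    M <- matrix(0, n, length(pwIds), dimnames = list(ids, pwIds))
    for (g in intersect(names(pw), ids))
      if (length(pw[[g]])) M[g, pw[[g]]] <- 1
    S <- (M %*% t(M)) > 0
    unann <- rowSums(M) == 0
    S[unann, ] <- NA; S[, unann] <- NA
    out$shares_pathway <- S
    ed <- corpus@ppiEdges
    A <- matrix(0, n, n, dimnames = list(ids, ids))
    if (nrow(ed)) {
      ia <- match(ed$gene_a, ids); ib <- match(ed$gene_b, ids)
      ok <- !is.na(ia) & !is.na(ib)
      A[cbind(ia[ok], ib[ok])] <- 1
      A[cbind(ib[ok], ia[ok])] <- 1
    }
    Sppi <- if (ppiMode == "direct") A > 0 else (A %*% A) > 0
    deg0 <- rowSums(A) == 0
    Sppi[deg0, ] <- NA; Sppi[, deg0] <- NA
    out$shares_ppi <- Sppi
    if (!is.null(index)) {
      G <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
      usable <- rownames(index@termSim)
      sets <- lapply(ids, function(g)
        intersect(unique(corpus@goAnnotations[[g]]), usable))
      annIdx <- which(lengths(sets) > 0)
      if (length(annIdx)) {
        # many genes share identical term sets: compute the BMA once
        # per distinct set signature and expand
        sig <- vapply(sets[annIdx], function(s)
          paste(sort(s), collapse = "|"), character(1))
        uSig <- unique(sig)
        uSets <- sets[annIdx][match(uSig, sig)]
        ts <- index@termSim
        nu <- length(uSig)
        uBma <- matrix(NA_real_, nu, nu)
        for (i in seq_len(nu)) {
          for (j in i:nu) {
            m <- ts[uSets[[i]], uSets[[j]], drop = FALSE]
            rmax <- m[cbind(seq_len(nrow(m)), max.col(m))]
            cmax <- m[cbind(max.col(t(m)), seq_len(ncol(m)))]
            uBma[i, j] <- uBma[j, i] <-
              (sum(rmax) + sum(cmax)) / (nrow(m) + ncol(m))
          }
        }
        si <- match(sig, uSig)
        G[annIdx, annIdx] <- uBma[si, si]
      }
      out$go_sim <- G
    }
  }
  out
}

# Attach metric columns to a pair table by matrix lookup.
.lookupMetrics <- function(pairs, mats) {
  ia <- match(pairs$gene_a, mats$ids)
  ib <- match(pairs$gene_b, mats$ids)
  at <- function(m) m[cbind(ia, ib)]
  if (!is.null(mats$correlation)) pairs$correlation <- at(mats$correlation)
  if (!is.null(mats$is_paralog)) pairs$is_paralog <- at(mats$is_paralog)
  if (!is.null(mats$shares_pathway))
    pairs$shares_pathway <- at(mats$shares_pathway)
  if (!is.null(mats$shares_ppi)) pairs$shares_ppi <- at(mats$shares_ppi)
  if (!is.null(mats$go_sim)) pairs$go_sim <- at(mats$go_sim)
  pairs
}

.defaultBinEdges <- function() c(0, 10^seq(4, 7, by = 0.5))

.binLabels <- function(edges) {
  c(sprintf("[%g,%g)", edges[-length(edges)], edges[-1L]),
    sprintf("[%g,Inf)", edges[length(edges)]))
}

.binAssign <- function(d, edges) {
  i <- findInterval(d, edges)
  i[i < 1L] <- 1L                       # below the first edge: first bin
  factor(.binLabels(edges)[i], levels = .binLabels(edges))
}

.binSummaries <- function(pairs, bins) {
  lv <- levels(bins)
  out <- data.frame(bin = lv, n_pairs = as.integer(table(bins)[lv]))
  summarise <- function(v, f) {
    s <- rep(NA_real_, length(lv))
    ok <- !is.na(v)
    if (any(ok)) {
      agg <- tapply(v[ok], bins[ok], f)
      s[match(names(agg), lv)] <- agg
    }
    s
  }
  if (!is.null(pairs$correlation))
    out$median_correlation <- summarise(pairs$correlation, stats::median)
  if (!is.null(pairs$go_sim))
    out$median_go_sim <- summarise(pairs$go_sim, stats::median)
  if (!is.null(pairs$shares_pathway))
    out$n_shared_pathway <- summarise(as.numeric(pairs$shares_pathway), sum)
  if (!is.null(pairs$shares_ppi))
    out$n_shared_ppi <- summarise(as.numeric(pairs$shares_ppi), sum)
  out
}

#' Distance-binned pair summaries with gene-identity permutation testing
#'
#' Assigns every same-chromosome gene pair to a linear-distance bin, then
#' compares the per-bin metric summaries (median correlation, median GO
#' similarity, counts of pairs sharing a pathway / PPI) of the real genome
#' against the same summaries recomputed on \code{nRandomGenomes}
#' within-chromosome gene-identity permutations. Per bin and metric the
#' one-sided permutation p-value is (number of random genomes with a
#' summary >= the real value) / N, FDR-corrected across bins within each
#' metric.
#'
#' @param genome A \code{GenomeModel}.
#' @param expr Optional expression matrix.
#' @param corpus Optional \code{AnnotationCorpus}.
#' @param index Optional \code{OntologyIndex}.
#' @param binEdges Increasing distance bin edges in bp; pairs beyond the
#'   last edge land in an overflow bin. Default log-spaced 10 kb - 10 Mb.
#' @param nRandomGenomes Number of permuted genomes (default 1000).
#' @param seed Seed for the permutations.
#' @param mask Optional gene ids excluded up front.
#' @param dropParalogs Remove paralogous pairs first (default TRUE).
#' @param ppiMode Passed to \code{\link{sharedPpi}}.
#' @return list(real, p, fdr): per-bin real summaries and matching
#'   permutation p-value / FDR tables.
#' @export
genomewideDistanceBins <- function(genome, expr = NULL, corpus = NULL,
                                   index = NULL,
                                   binEdges = .defaultBinEdges(),
                                   nRandomGenomes = 1000, seed = 1,
                                   mask = NULL, dropParalogs = TRUE,
                                   ppiMode = "direct", mats = NULL) {
  if (is.null(mats))
    mats <- pairMetricMatrices(genome, expr, corpus, index, ppiMode)
  pairs <- allGenePairs(genome, mask = mask)
  if (dropParalogs && !is.null(mats$is_paralog)) {
    pairs <- .lookupMetrics(pairs, mats[c("ids", "is_paralog")])
    pairs <- pairs[!pairs$is_paralog, , drop = FALSE]
    pairs$is_paralog <- NULL
  }
  bins <- .binAssign(pairs$distance, binEdges)
  real <- .binSummaries(.lookupMetrics(pairs, mats), bins)
  metricCols <- setdiff(names(real), c("bin", "n_pairs"))
  if (!length(metricCols) || !nRandomGenomes)
    return(list(real = real, p = NULL, fdr = NULL))
  geneIds <- genes(genome)$gene_id
  chr <- as.character(seqnames(genes(genome)))
  ia <- match(pairs$gene_a, geneIds)
  ib <- match(pairs$gene_b, geneIds)
  nullSumm <- array(NA_real_, dim = c(nRandomGenomes, nrow(real),
                                      length(metricCols)),
                    dimnames = list(NULL, real$bin, metricCols))
  .withSeed(seed, function() {
    for (k in seq_len(nRandomGenomes)) {
      ids <- geneIds
      for (c in unique(chr)) {
        i <- which(chr == c)
        ids[i] <- ids[i][sample.int(length(i))]
      }
      pk <- data.frame(gene_a = ids[ia], gene_b = ids[ib],
                       stringsAsFactors = FALSE)
      pk <- .lookupMetrics(pk, mats)
      s <- .binSummaries(cbind(pk, distance = pairs$distance), bins)
      for (m in metricCols) nullSumm[k, , m] <<- s[[m]]
    }
  })
  pTab <- real[, c("bin", "n_pairs")]
  fdrTab <- pTab
  for (m in metricCols) {
    p <- vapply(seq_len(nrow(real)), function(i) {
      rv <- real[[m]][i]
      nv <- nullSumm[, i, m]
      nv <- nv[!is.na(nv)]
      if (is.na(rv) || !length(nv)) return(NA_real_)
      permutationP(rv, nv)
    }, numeric(1))
    pTab[[m]] <- p
    adj <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    if (any(ok)) adj[ok] <- bhFdr(p[ok])
    fdrTab[[m]] <- adj
  }
  list(real = real, p = pTab, fdr = fdrTab)
}
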