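# Full-analysis orchestration: ingest/simulate -> annotate -> randomise ->
# pairwise metrics -> ensemble tests -> report bundle. Deterministic given
# the master seed.

.metricValues <- function(pairs, metric) {
  col <- switch(metric, correlation = "correlation", go_sim = "go_sim",
                pathway = "shares_pathway", ppi = "shares_ppi",
                distance = "distance", stop("unknown metric"))
  v <- pairs[[col]]
  if (is.null(v)) v <- logical(0)
  v <- v[!is.na(v)]
  if (metric %in% c("pathway", "ppi"))
    c(hits = sum(v), other = sum(!v))
  else v
}

.restrictTadSet <- function(x, ids, bySource = FALSE) {
  gr <- tads(x)
  keep <- if (bySource) gr$source_id %in% ids else gr$tad_id %in% ids
  S4Vectors::new2("TADSet", tads = gr[keep], style = tadStyle(x),
                  provenance = provenance(x), binSize = binSize(x),
                  check = FALSE)
}

#' Run the full TAD null-model analysis pipeline
#'
#' Annotates the TADs, builds positional-randomisation and
#' genome-randomisation null ensembles, and runs every configured
#' real-vs-null comparison with the median-p ensemble scheme. For
#' comparisons restricted to CTCF TADs, each random TAD inherits its
#' source TAD's CTCF label (the equivalent random TADs are compared, not a
#' re-classification). The functional-similarity analyses default to CTCF
#' TADs with paralog pairs and masked (olfactory) genes removed.
#'
#' @param data list(genome, tads, peaks, compartments, expression, corpus)
#'   as produced by \code{\link{simulateAll}} or the readers.
#' @param nSets Null sets per ensemble (standard: 100).
#' @param seed Master seed; the whole run is reproducible from it.
#' @param nonNestedProb,maxAttempts Positional-randomiser settings.
#' @param restrictCtcf Restrict functional comparisons to CTCF TADs.
#' @param dropParalogs Remove paralogous pairs from functional comparisons.
#' @param applyMask Remove masked (olfactory) genes from functional
#'   comparisons.
#' @param minTadBp Minimum TAD size filter applied up front (0 = off).
#' @param excludeChroms Chromosomes excluded up front.
#' @param binEdges Distance-bin edges for the genome-wide permutation
#'   analysis.
#' @param nRandomGenomes Random genomes for the distance-bin analysis
#'   (standard: 1000; 0 disables the analysis).
#' @param ppiMode Passed to \code{\link{sharedPpi}}.
#' @param analyses Character vector selecting the analyses to run.
#' @return A named list (report bundle): TAD annotations, pair tables,
#'   \code{ComparisonResult}s, permutation tables, convergence reports,
#'   cross-tabulations and exclusion logs.
#' @export
runPipeline <- function(data, nSets = 100, seed = 1, nonNestedProb = 0.1,
                        maxAttempts = 10000, restrictCtcf = TRUE,
                        dropParalogs = TRUE, applyMask = TRUE,
                        minTadBp = 0, excludeChroms = c("chrX", "chrY"),
                        binEdges = .defaultBinEdges(),
                        nRandomGenomes = 1000, ppiMode = "direct",
                        analyses = c("distance", "ctcf", "paralog",
                                     "constraint", "coexpression",
                                     "gosim", "pathway", "ppi",
                                     "distance_bins", "convergence",
                                     "compartments")) {
  stopifnot(is(data$genome, "GenomeModel"), is(data$tads, "TADSet"))
  genome <- excludeChromosomes(data$genome, excludeChroms)
  tadsReal <- excludeChromosomes(data$tads, excludeChroms)
  if (minTadBp > 0)
    tadsReal <- suppressMessages(filterMinSize(tadsReal, minTadBp))
  corpus <- data$corpus
  expr <- data$expression
  seeds <- .withSeed(seed, function() sample.int(2^31 - 2, 3))
  bundle <- list(config = list(nSets = nSets, seed = seed,
                               nonNestedProb = nonNestedProb,
                               maxAttempts = maxAttempts,
                               restrictCtcf = restrictCtcf,
                               dropParalogs = dropParalogs,
                               applyMask = applyMask,
                               analyses = analyses))

  annot <- annotateTads(tadsReal, genome, peaks = data$peaks,
                        track = data$compartments, corpus = corpus)
  bundle$annotations <- annot

  needPos <- any(c("distance", "ctcf", "paralog", "coexpression",
                   "gosim", "pathway", "ppi", "convergence") %in% analyses)
  needGen <- any(c("constraint", "coexpression", "gosim", "pathway",
                   "ppi") %in% analyses)
  ensPos <- if (needPos)
    buildEnsemble(tadsReal, genome, method = "positional", nSets = nSets,
                  seed = seeds[1], nonNestedProb = nonNestedProb,
                  maxAttempts = maxAttempts) else NULL
  ensGen <- if (needGen)
    buildEnsemble(tadsReal, genome, method = "genome", nSets = nSets,
                  seed = seeds[2]) else NULL
  if (needPos)
    bundle$exclusions <- list(positional = excludedCounts(ensPos))

  mask <- if (applyMask && !is.null(corpus)) corpus@maskGenes else character()
  genomeMasked <- applyGeneMask(genome, mask)

  ctcfIds <- NULL
  if (!is.null(annot$ctcf_class))
    ctcfIds <- annot$tad_id[annot$ctcf_class == "CTCF"]
  funcTads <- tadsReal
  if (restrictCtcf && length(ctcfIds))
    funcTads <- .restrictTadSet(tadsReal, ctcfIds)

  index <- NULL
  if (!is.null(corpus) && nrow(corpus@ontologyEdges))
    index <- buildOntologyIndex(corpus)
  mats <- pairMetricMatrices(genome, expr = expr, corpus = corpus,
                             index = index, ppiMode = ppiMode)

  # One gene-assignment map per TAD set; every pair table below derives
  # from these (the nested/overlap pair deduplication is in the union).
  gAll <- genes(genome)
  geneIds <- gAll$gene_id
  starts0 <- setNames(start(gAll) - 1, geneIds)
  realMap <- assignGenes(tadsReal, genome)
  nullMaps <- if (needPos)
    lapply(nullSets(ensPos), function(s) assignGenes(s, genome)) else list()

  flagP <- function(p) {
    if (is.null(mats$is_paralog)) p$is_paralog <- FALSE
    else p <- .lookupMetrics(p, mats[c("ids", "is_paralog")])
    p
  }
  finishPairs <- function(p) {
    p <- applyGeneMask(.lookupMetrics(p, mats), mask)
    if (dropParalogs && !is.null(p$is_paralog))
      p <- p[!p$is_paralog, , drop = FALSE]
    p
  }
  nullTadIds <- function(s, srcIds) {
    gr <- tads(s)
    gr$tad_id[gr$source_id %in% srcIds]
  }

  # full (unrestricted, unfiltered) pair table for distance and paralogy
  pairsAll <- flagP(.pairsFromMap(realMap, starts0))
  nullPairsAll <- lapply(nullMaps, function(m)
    flagP(.pairsFromMap(m, starts0)))

  if ("distance" %in% analyses) {
    bundle$intergene_distance <- ensembleCompare(
      pairsAll$distance,
      lapply(nullPairsAll, function(p) p$distance),
      test = "wilcoxon", statistic = "intergene_distance")
  }

  if ("ctcf" %in% analyses && length(data$peaks)) {
    fracCtcf <- function(ts) {
      cl <- classifyCtcf(ts, data$peaks, windowBp = binSize(ts))
      mean(cl$ctcf_class == "CTCF")
    }
    bundle$ctcf_boundary_fraction <- list(
      real = fracCtcf(tadsReal),
      null = vapply(nullSets(ensPos), fracCtcf, numeric(1)))
  }

  if ("paralog" %in% analyses && !is.null(corpus) &&
      nrow(corpus@paralogPairs)) {
    paraCounts <- function(p) {
      c(hits = sum(p$is_paralog), other = sum(!p$is_paralog))
    }
    bundle$paralog_enrichment <- ensembleCompare(
      paraCounts(pairsAll), lapply(nullPairsAll, paraCounts),
      test = "fisher", statistic = "paralog_enrichment")
    if (length(ctcfIds)) {
      splitCmp <- function(ids, label) {
        realP <- flagP(.pairsFromMap(realMap, starts0, tadIds = ids))
        nullP <- lapply(seq_along(nullMaps), function(k)
          flagP(.pairsFromMap(nullMaps[[k]], starts0,
                              tadIds = nullTadIds(nullSets(ensPos)[[k]],
                                                  ids))))
        ok <- nrow(realP) > 0 && all(vapply(nullP, nrow, integer(1)) > 0)
        if (!ok) return(NULL)
        ensembleCompare(paraCounts(realP), lapply(nullP, paraCounts),
                        test = "fisher", statistic = label)
      }
      nonIds <- setdiff(annot$tad_id, ctcfIds)
      bundle$paralog_enrichment_ctcf <-
        splitCmp(ctcfIds, "paralog_enrichment_ctcf")
      bundle$paralog_enrichment_nonctcf <-
        splitCmp(nonIds, "paralog_enrichment_nonctcf")
    }
  }

  if ("constraint" %in% analyses && !is.null(corpus) &&
      nrow(corpus@constraint)) {
    mc <- meanConstraint(tadsReal, genome, corpus)
    cls <- suppressMessages(occupancyClasses(
      annot$n_genes[match(mc$tad_id, annot$tad_id)]))
    summ <- data.frame(tad_id = mc$tad_id, occupancy_class = cls,
                       mean_constraint = mc$mean_constraint)
    bundle$occupancy_constraint <- summ
    enough <- sum(table(summ$occupancy_class) >= 2) >= 2
    if (enough)
      bundle$occupancy_constraint_fdr <-
        suppressWarnings(occupancyConstraintTests(summ))
    singReal <- summ$mean_constraint[summ$occupancy_class == "1"]
    if (length(singReal) >= 2) {
      # gene identities permute but positions (hence occupancy) do not:
      # the singleton-TAD gene positions are permutation-invariant
      cons <- corpus@constraint
      sByG <- split(cons$score, cons$gene_id)
      cSum <- vapply(sByG, sum, numeric(1))
      cN <- vapply(sByG, length, numeric(1))
      singletonTads <- annot$tad_id[!is.na(annot$n_genes) &
                                    annot$n_genes == 1L]
      singPos <- match(unlist(realMap$byTad[singletonTads],
                              use.names = FALSE), geneIds)
      singNull <- lapply(nullSets(ensGen), function(gperm) {
        ids1 <- genes(gperm)$gene_id[singPos]
        v <- cSum[ids1] / cN[ids1]
        v[!is.na(v)]
      })
      if (all(vapply(singNull, length, integer(1)) >= 2))
        bundle$singleton_constraint_vs_random_genome <- ensembleCompare(
          singReal, singNull, test = "wilcoxon",
          statistic = "singleton_constraint_vs_random_genome")
    }
  }

  # functional similarity comparisons (CTCF-restricted by default)
  funcMetrics <- intersect(analyses,
                           c("coexpression", "gosim", "pathway", "ppi"))
  if (length(funcMetrics)) {
    funcIds <- tads(funcTads)$tad_id
    funcPairsRaw <- .pairsFromMap(realMap, starts0, tadIds = funcIds)
    realPairs <- finishPairs(funcPairsRaw)
    bundle$pairs <- realPairs
    nullPairsPos <- lapply(seq_along(nullMaps), function(k) {
      ids <- if (restrictCtcf && length(ctcfIds))
        nullTadIds(nullSets(ensPos)[[k]], ctcfIds) else NULL
      finishPairs(.pairsFromMap(nullMaps[[k]], starts0, tadIds = ids))
    })
    # genome permutations keep every position: substitute identities into
    # the real position-pair template
    ia0 <- match(funcPairsRaw$gene_a, geneIds)
    ib0 <- match(funcPairsRaw$gene_b, geneIds)
    nullPairsGen <- lapply(nullSets(ensGen), function(gperm) {
      permIds <- genes(gperm)$gene_id
      a <- permIds[ia0]; b <- permIds[ib0]
      swap <- a > b
      tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
      finishPairs(data.frame(gene_a = a, gene_b = b,
                             distance = funcPairsRaw$distance,
                             stringsAsFactors = FALSE))
    })
    metricOf <- c(coexpression = "correlation", gosim = "go_sim",
                  pathway = "pathway", ppi = "ppi")
    testOf <- c(coexpression = "wilcoxon", gosim = "wilcoxon",
                pathway = "fisher", ppi = "fisher")
    for (a in funcMetrics) {
      m <- metricOf[[a]]
      rv <- .metricValues(realPairs, m)
      nvPos <- lapply(nullPairsPos, .metricValues, metric = m)
      nvGen <- lapply(nullPairsGen, .metricValues, metric = m)
      okDist <- function(v) if (testOf[[a]] == "wilcoxon") length(v) >= 2
                            else sum(v) > 0
      if (!okDist(rv) || !all(vapply(nvPos, okDist, logical(1))) ||
          !all(vapply(nvGen, okDist, logical(1)))) next
      bundle[[paste0(a, "_vs_random_tads")]] <- ensembleCompare(
        rv, nvPos, test = testOf[[a]],
        statistic = paste0(a, "_vs_random_tads"))
      bundle[[paste0(a, "_vs_random_genome")]] <- ensembleCompare(
        rv, nvGen, test = testOf[[a]],
        statistic = paste0(a, "_vs_random_genome"))
    }
  }

  if ("distance_bins" %in% analyses && nRandomGenomes > 0) {
    bundle$distance_bins <- genomewideDistanceBins(
      genomeMasked, expr = expr, corpus = corpus, index = index,
      binEdges = binEdges, nRandomGenomes = nRandomGenomes,
      seed = seeds[3], dropParalogs = dropParalogs, ppiMode = ppiMode,
      mats = mats)
  }

  if ("convergence" %in% analyses && !is.null(bundle$intergene_distance)) {
    bundle$convergence <- convergenceReport(
      perSetPValues(bundle$intergene_distance), tol = 0.05)
  }

  if ("compartments" %in% analyses && !is.null(annot$compartment) &&
      !is.null(annot$ctcf_class)) {
    bundle$ctcf_by_compartment <- table(ctcf = annot$ctcf_class,
                                        compartment = annot$compartment)
  }

  if (!is.null(data$tadsB))
    bundle$caller_concordance <- callerConcordance(tadsReal, data$tadsB)

  bundle
}

#' Render a report bundle as human-readable text
#'
#' Tables carry the usual significance stars (p < 0.001 = ***, p < 0.01 =
#' **, p < 0.05 = *, otherwise NS); empty sections are omitted with a
#' note. Every number shown is taken from the bundle (no report-only
#' computation).
#'
#' @param bundle Output of \code{\link{runPipeline}}.
#' @return Character vector of report lines (invisibly printed with cat
#'   when interactive).
#' @export
renderReport <- function(bundle) {
  lines <- c("TAD null-model analysis report",
             sprintf("null sets per ensemble: %d; master seed: %d",
                     bundle$config$nSets, bundle$config$seed), "")
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    if (is(x, "ComparisonResult")) {
      pTxt <- if (medianP(x) == 0)
        sprintf("< %.3g", 1 / length(perSetPValues(x)))
      else sprintf("%.4g", medianP(x))
      lines <- c(lines, sprintf(
        "%-42s median p = %-10s %-3s median r = %+.3f (n sets = %d)",
        x@statistic, pTxt, x@stars, medianEffectSize(x), x@nNullSets))
    }
  }
  if (!is.null(bundle$ctcf_boundary_fraction)) {
    f <- bundle$ctcf_boundary_fraction
    lines <- c(lines, sprintf(
      "%-42s real = %.1f%%, median random = %.1f%%",
      "ctcf_both_boundary_fraction", 100 * f$real,
      100 * stats::median(f$null)))
  }
  if (!is.null(bundle$occupancy_constraint_fdr)) {
    m <- bundle$occupancy_constraint_fdr
    lines <- c(lines, "", "occupancy-class constraint contrasts (FDR-adjusted p):")
    for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):ncol(m)) {
      if (!is.na(m[i, j]))
        lines <- c(lines, sprintf("  class %s vs %s: p_adj = %.4g %s",
                                  rownames(m)[i], colnames(m)[j],
                                  m[i, j], starsFor(m[i, j])))
    }
  }
  if (!is.null(bundle$distance_bins) && !is.null(bundle$distance_bins$fdr)) {
    lines <- c(lines, "", "distance-binned permutation tests (FDR-adjusted):")
    fdr <- bundle$distance_bins$fdr
    for (m in setdiff(names(fdr), c("bin", "n_pairs"))) {
      sig <- which(!is.na(fdr[[m]]) & fdr[[m]] < 0.05)
      lines <- c(lines, sprintf("  %s: %d/%d bins significant", m,
                                length(sig), sum(!is.na(fdr[[m]]))))
    }
  }
  if (!is.null(bundle$convergence)) {
    cv <- bundle$convergence
    lines <- c(lines, "", sprintf(
      "convergence: running median stabilises at set %s of %d (final %.4g)",
      ifelse(is.na(cv$stabilizationIndex), "NA", cv$stabilizationIndex),
      length(cv$trace), cv$finalMedian))
  }
  keyOf <- c(distance = "intergene_distance",
             ctcf = "ctcf_boundary_fraction",
             paralog = "paralog_enrichment",
             constraint = "occupancy_constraint",
             coexpression = "coexpression_vs_random_tads",
             gosim = "gosim_vs_random_tads",
             pathway = "pathway_vs_random_tads",
             ppi = "ppi_vs_random_tads",
             distance_bins = "distance_bins",
             convergence = "convergence",
             compartments = "ctcf_by_compartment")
  requested <- intersect(bundle$config$analyses, names(keyOf))
  skipped <- requested[!(keyOf[requested] %in% names(bundle))]
  if (length(skipped))
    lines <- c(lines, "", sprintf(
      "note: analysis '%s' produced no result (insufficient input)",
      skipped))
  lines
}

#' Write a report bundle to disk (TSV + JSON)
#'
#' @param bundle Output of \code{\link{runPipeline}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bundle$annotations,
                     file.path(dir, "tad_annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$pairs))
    utils::write.table(bundle$pairs, file.path(dir, "pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  res <- list()
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    if (is(x, "ComparisonResult"))
      res[[nm]] <- list(median_p = medianP(x),
                        median_r = medianEffectSize(x),
                        stars = x@stars, n_sets = x@nNullSets,
                        per_set_p = perSetPValues(x))
  }
  jsonlite::write_json(res, file.path(dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(renderReport(bundle), file.path(dir, "report.txt"))
  invisible(dir)
}
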