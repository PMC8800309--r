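#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps pintersect reduce
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
#'   keepSeqlevels seqlengths<-
NULL

#' GenomeModel: chromosomes and protein-coding gene coordinates
#'
#' The substrate every randomisation acts on: a set of chromosomes with
#' lengths and a table of protein-coding genes. Gene coordinates are held
#' as a \link[GenomicRanges]{GRanges} (1-based, closed intervals) whose
#' seqinfo carries the chromosome lengths.
#'
#' @slot genes A \code{GRanges} with a \code{gene_id} metadata column,
#'   sorted by (chromosome, start).
#' @export
setClass("GenomeModel", representation(genes = "GRanges"))

S4Vectors::setValidity2("GenomeModel", function(object) {
  g <- object@genes
  msg <- character()
  if (is.null(g$gene_id)) {
    msg <- c(msg, "genes must carry a 'gene_id' metadata column")
  } else {
    if (anyDuplicated(g$gene_id))
      msg <- c(msg, "duplicate gene_id values are not allowed")
  }
  sl <- seqlengths(g)
  if (any(is.na(sl)))
    msg <- c(msg, "all chromosomes must have a known length")
  if (length(g)) {
    if (any(start(g) < 1L))
      msg <- c(msg, "gene start before chromosome start")
    lim <- sl[as.character(seqnames(g))]
    if (any(end(g) > lim))
      msg <- c(msg, "gene end beyond chromosome length")
    if (any(width(g) < 1L))
      msg <- c(msg, "gene start must precede gene end")
  }
  if (length(msg)) msg else TRUE
})

#' TADSet: a collection of TAD intervals with style and provenance
#'
#' @slot tads A \code{GRanges} with a \code{tad_id} metadata column.
#' @slot style Either \code{"partition"} (non-overlapping, TopDom-like) or
#'   \code{"overlapping"} (nested/overlapping, Arrowhead-like).
#' @slot provenance One of \code{"real"}, \code{"random_positional"},
#'   \code{"random_genome"}, \code{"random_nora"}, \code{"random_rao"}.
#' @slot binSize Hi-C bin size in bp (default 10000); the unit of the
#'   boundary-tolerance arguments elsewhere.
#' @export
setClass("TADSet", representation(
  tads = "GRanges", style = "character",
  provenance = "character", binSize = "numeric"
))

.TAD_STYLES <- c("partition", "overlapping")
.TAD_PROVENANCE <- c("real", "random_positional", "random_genome",
                     "random_nora", "random_rao")

S4Vectors::setValidity2("TADSet", function(object) {
  msg <- character()
  t <- object@tads
  if (!object@style %in% .TAD_STYLES)
    msg <- c(msg, sprintf("style must be one of: %s",
                          paste(.TAD_STYLES, collapse = ", ")))
  if (!object@provenance %in% .TAD_PROVENANCE)
    msg <- c(msg, sprintf("provenance must be one of: %s",
                          paste(.TAD_PROVENANCE, collapse = ", ")))
  if (is.null(t$tad_id))
    msg <- c(msg, "tads must carry a 'tad_id' metadata column")
  if (length(t) && any(width(t) < 1L))
    msg <- c(msg, "TAD start must precede TAD end")
  if (identical(object@style, "partition") && length(t) > 1L) {
    hits <- findOverlaps(t, minoverlap = 1L, drop.self = TRUE,
                         drop.redundant = TRUE)
    if (length(hits))
      msg <- c(msg, "partition-style TAD sets must not contain overlapping intervals")
  }
  if (object@binSize <= 0)
    msg <- c(msg, "binSize must be positive")
  if (length(msg)) msg else TRUE
})

#' AnnotationCorpus: gene-level functional annotation tables
#'
#' Bundles every annotation resource the pairwise similarity metrics
#' consume: GO term assignments and the ontology parent-edge list, pathway
#' memberships, physical PPI edges, paralog pairs, an ID mask (olfactory
#' genes), and per-transcript constraint scores (nonsynonymous z-scores).
#'
#' @slot goAnnotations Named list: gene id -> character vector of term ids.
#' @slot ontologyEdges data.frame(child, parent): rooted-DAG edge list.
#' @slot pathways Named list: gene id -> character vector of pathway ids.
#' @slot ppiEdges data.frame(gene_a, gene_b): unordered physical edges.
#' @slot paralogPairs data.frame(gene_a, gene_b): unordered paralog pairs.
#' @slot maskGenes Character vector of gene ids to mask when requested.
#' @slot constraint data.frame(transcript_id, gene_id, score).
#' @export
setClass("AnnotationCorpus", representation(
  goAnnotations = "list", ontologyEdges = "data.frame",
  pathways = "list", ppiEdges = "data.frame",
  paralogPairs = "data.frame", maskGenes = "character",
  constraint = "data.frame"
))

S4Vectors::setValidity2("AnnotationCorpus", function(object) {
  msg <- character()
  .chkPairs <- function(df, what) {
    if (nrow(df) && any(df[[1L]] == df[[2L]]))
      sprintf("%s must not contain self-pairs", what) else character()
  }
  if (nrow(object@ppiEdges) && ncol(object@ppiEdges) >= 2L)
    msg <- c(msg, .chkPairs(object@ppiEdges, "ppiEdges"))
  if (nrow(object@paralogPairs) && ncol(object@paralogPairs) >= 2L)
    msg <- c(msg, .chkPairs(object@paralogPairs, "paralogPairs"))
  if (nrow(object@ontologyEdges)) {
    if (!all(c("child", "parent") %in% names(object@ontologyEdges)))
      msg <- c(msg, "ontologyEdges needs 'child' and 'parent' columns")
  }
  if (nrow(object@constraint) &&
      !all(c("transcript_id", "gene_id", "score") %in% names(object@constraint)))
    msg <- c(msg, "constraint needs transcript_id, gene_id, score columns")
  if (length(msg)) msg else TRUE
})

#' OntologyIndex: information content and ancestor closure for GO terms
#'
#' @slot ic Named numeric: normalised information content per term, in
#'   [0, 1] with IC(root) = 0.
#' @slot ancestors Named list: term -> reflexive ancestor set.
#' @slot termSim Precomputed Jiang similarity matrix over all indexed
#'   terms (terms x terms).
#' @slot root The root term id.
#' @export
setClass("OntologyIndex", representation(
  ic = "numeric", ancestors = "list", termSim = "matrix", root = "character"
))

#' NullEnsemble: N independently randomised TAD sets or genomes
#'
#' @slot sets List of \code{TADSet} (interval randomisers) or
#'   \code{GenomeModel} (genome randomiser), one per replicate set.
#' @slot method The randomiser that produced the sets.
#' @slot seeds Integer sub-seed used for each set.
#' @slot excluded Integer count of source TADs excluded per set (placement
#'   not found within the attempt budget).
#' @slot masterSeed The master seed the sub-seeds derive from.
#' @export
setClass("NullEnsemble", representation(
  sets = "list", method = "character", seeds = "integer",
  excluded = "integer", masterSeed = "integer"
))

S4Vectors::setValidity2("NullEnsemble", function(object) {
  msg <- character()
  n <- length(object@sets)
  if (length(object@seeds) != n)
    msg <- c(msg, "one recorded seed per set required")
  if (length(object@excluded) != n)
    msg <- c(msg, "one exclusion count per set required")
  if (length(msg)) msg else TRUE
})

#' ComparisonResult: real-vs-null ensemble test summary
#'
#' The ensemble testing scheme: the real-data value distribution is tested
#' against each null set separately and the median p-value and median
#' signed effect size r over the ensemble are reported.
#'
#' @slot statistic Name of the comparison.
#' @slot realSummary Summary of the real data (e.g. its median).
#' @slot pValues Per-null-set p-values.
#' @slot effectSizes Per-null-set signed effect sizes r (positive when the
#'   TAD-side values exceed the null side).
#' @slot medianP Median of \code{pValues}.
#' @slot medianEffectSize Median of \code{effectSizes}.
#' @slot nNullSets Number of null sets compared against.
#' @slot stars Significance string for \code{medianP} at the 0.05 / 0.01 /
#'   0.001 thresholds ("NS" when not significant).
#' @export
setClass("ComparisonResult", representation(
  statistic = "character", realSummary = "numeric", pValues = "numeric",
  effectSizes = "numeric", medianP = "numeric",
  medianEffectSize = "numeric", nNullSets = "integer", stars = "character"
))

S4Vectors::setValidity2("ComparisonResult", function(object) {
  msg <- character()
  p <- object@pValues
  if (length(p) && (any(p < 0 | p > 1, na.rm = TRUE)))
    msg <- c(msg, "p-values must lie in [0, 1]")
  r <- object@effectSizes
  if (length(r) && any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "effect sizes r must lie in [-1, 1]")
  if (length(p) != object@nNullSets)
    msg <- c(msg, "median must be taken over exactly nNullSets p-values")
  if (length(msg)) msg else TRUE
})

# ---- show methods -----------------------------------------------------

setMethod("show", "GenomeModel", function(object) {
  sl <- seqlengths(object@genes)
  cat(sprintf("GenomeModel: %d chromosome(s), %d gene(s)\n",
              length(sl), length(object@genes)))
})

setMethod("show", "TADSet", function(object) {
  cat(sprintf("TADSet: %d TAD(s), style=%s, provenance=%s, binSize=%g\n",
              length(object@tads), object@style, object@provenance,
              object@binSize))
})

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf("NullEnsemble: %d set(s), method=%s, total excluded=%d\n",
              length(object@sets), object@method, sum(object@excluded)))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult '%s': median p = %.4g (%s), median r = %.3f over %d null sets\n",
              object@statistic, object@medianP, object@stars,
              object@medianEffectSize, object@nNullSets))
})

setMethod("show", "AnnotationCorpus", function(object) {
  cat(sprintf(paste0(
    "AnnotationCorpus: %d GO-annotated gene(s), %d ontology edge(s), ",
    "%d pathway-annotated gene(s),\n  %d PPI edge(s), %d paralog pair(s), ",
    "%d masked gene(s), %d constraint row(s)\n"),
    length(object@goAnnotations), nrow(object@ontologyEdges),
    length(object@pathways), nrow(object@ppiEdges),
    nrow(object@paralogPairs), length(object@maskGenes),
    nrow(object@constraint)))
})

setMethod("show", "OntologyIndex", function(object) {
  cat(sprintf("OntologyIndex: %d term(s), root=%s\n",
              length(object@ic), object@root))
})
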