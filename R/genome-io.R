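# Readers, writers and input filters for every table the pipeline consumes.
# Internal convention: 1-based closed GRanges coordinates. BED input/output
# is 0-based half-open and converted at the boundary; gene tables follow the
# Ensembl 1-based inclusive convention.

.readTsv <- function(path, required, what) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: '%s'", what, path), call. = FALSE)
  if (file.size(path) == 0L) {
    warning(sprintf("%s file '%s' is empty", what, path), call. = FALSE)
    df <- as.data.frame(setNames(rep(list(character()), length(required)),
                                 required))
    return(df)
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = ""),
    error = function(e) stop(sprintf("failed to parse %s file '%s': %s",
                                     what, path, conditionMessage(e)),
                             call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s file '%s' lacks required column(s): %s",
                 what, path, paste(missing, collapse = ", ")),
         call. = FALSE)
  df
}

.checkNumericColumn <- function(df, col, what) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]))
  if (length(bad))
    stop(sprintf("%s: non-numeric value in column '%s' at data line %d",
                 what, col, bad[1L]), call. = FALSE)
  v
}

#' Construct a GenomeModel
#'
#' @param geneTable data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive coordinates), or a
#'   \code{GRanges} with a \code{gene_id} column.
#' @param chromSizes Named numeric vector of chromosome lengths in bp, or
#'   data.frame with columns \code{chrom} and \code{length}.
#' @return A validated \code{GenomeModel}, genes sorted by (chrom, start).
#' @export
GenomeModel <- function(geneTable, chromSizes) {
  if (is.data.frame(chromSizes)) {
    if (!all(c("chrom", "length") %in% names(chromSizes)))
      stop("chromSizes data.frame needs 'chrom' and 'length' columns")
    chromSizes <- setNames(as.numeric(chromSizes$length),
                           as.character(chromSizes$chrom))
  }
  if (anyDuplicated(names(chromSizes)))
    stop("duplicate chromosome names in chromSizes")
  si <- Seqinfo(seqnames = names(chromSizes),
                seqlengths = as.integer(chromSizes))
  if (is(geneTable, "GRanges")) {
    gr <- geneTable
    if (is.null(gr$gene_id)) stop("gene GRanges needs a 'gene_id' column")
    unknown <- setdiff(unique(as.character(seqnames(gr))), names(chromSizes))
    if (length(unknown))
      stop(sprintf("gene(s) on unknown chromosome(s): %s",
                   paste(unknown, collapse = ", ")))
    gr <- GRanges(as.character(seqnames(gr)),
                  IRanges(start(gr), end(gr)),
                  gene_id = as.character(gr$gene_id), seqinfo = si)
  } else {
    df <- geneTable
    req <- c("gene_id", "chrom", "start", "end")
    if (!all(req %in% names(df)))
      stop(sprintf("gene table needs columns: %s", paste(req, collapse = ", ")))
    if (nrow(df)) {
      s <- .checkNumericColumn(df, "start", "gene table")
      e <- .checkNumericColumn(df, "end", "gene table")
      bad <- which(s > e)
      if (length(bad))
        stop(sprintf("gene table: start > end at data line %d (gene %s)",
                     bad[1L], df$gene_id[bad[1L]]))
      unknown <- setdiff(unique(as.character(df$chrom)), names(chromSizes))
      if (length(unknown))
        stop(sprintf("gene(s) on unknown chromosome(s): %s",
                     paste(unknown, collapse = ", ")))
      gr <- GRanges(as.character(df$chrom), IRanges(s, e),
                    gene_id = as.character(df$gene_id), seqinfo = si)
    } else {
      gr <- GRanges(seqinfo = si)
      gr$gene_id <- character()
    }
  }
  if (anyDuplicated(gr$gene_id))
    stop(sprintf("duplicate gene_id in input: %s",
                 paste(unique(gr$gene_id[duplicated(gr$gene_id)]),
                       collapse = ", ")))
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  new("GenomeModel", genes = gr)
}

#' Read a GenomeModel from TSV files
#'
#' Gene coordinates are interpreted as 1-based inclusive (the Ensembl
#' export convention).
#'
#' @param geneTablePath TSV with header columns gene_id, chrom, start, end.
#' @param chromSizesPath TSV with header columns chrom, length.
#' @return A validated \code{GenomeModel}.
#' @export
readGenome <- function(geneTablePath, chromSizesPath) {
  sizes <- .readTsv(chromSizesPath, c("chrom", "length"), "chromosome sizes")
  if (!nrow(sizes)) stop("chromosome sizes file contains no chromosomes")
  sizes$length <- .checkNumericColumn(sizes, "length", "chromosome sizes")
  genes <- .readTsv(geneTablePath, c("gene_id", "chrom", "start", "end"),
                    "gene table")
  if (!nrow(genes))
    warning("gene table is empty; returning a gene-free GenomeModel")
  GenomeModel(genes, sizes)
}

#' Construct a TADSet
#'
#' @param intervals \code{GRanges} (optionally with \code{tad_id}) or
#'   data.frame with columns chrom, start, end in 1-based closed
#'   coordinates.
#' @param style "partition" (non-overlapping) or "overlapping".
#' @param provenance Origin tag; default "real".
#' @param binSize Hi-C bin size in bp.
#' @return A validated \code{TADSet}. Duplicated identical intervals are
#'   collapsed with a warning; partition-style input with overlapping
#'   intervals is a validation error.
#' @export
TADSet <- function(intervals, style = c("partition", "overlapping"),
                   provenance = "real", binSize = 10000) {
  style <- match.arg(style)
  if (is.data.frame(intervals)) {
    gr <- GRanges(as.character(intervals$chrom),
                  IRanges(as.numeric(intervals$start),
                          as.numeric(intervals$end)))
    if (!is.null(intervals$tad_id)) gr$tad_id <- as.character(intervals$tad_id)
  } else gr <- intervals
  key <- paste(as.character(seqnames(gr)), start(gr), end(gr))
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicated identical TAD interval(s) collapsed",
                    sum(duplicated(key))))
    gr <- gr[!duplicated(key)]
  }
  if (is.null(gr$tad_id) || !length(gr)) {
    gr$tad_id <- if (length(gr)) sprintf("tad_%04d", seq_along(gr)) else character()
  }
  gr <- gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
  new("TADSet", tads = gr, style = style, provenance = provenance,
      binSize = binSize)
}

#' Read a TAD set from a BED file
#'
#' @param path BED3+ file (0-based half-open). A 4th column, when present,
#'   is used as the TAD id.
#' @param style "partition" or "overlapping"; partition style enforces
#'   pairwise non-overlap.
#' @param binSize Hi-C bin size in bp (default 10000).
#' @param provenance Origin tag; default "real".
#' @return A validated \code{TADSet}.
#' @export
readTads <- function(path, style = c("partition", "overlapping"),
                     binSize = 10000, provenance = "real") {
  style <- match.arg(style)
  gr <- rtracklayer::import(path, format = "BED")
  mc <- mcols(gr)
  gr2 <- GRanges(as.character(seqnames(gr)), IRanges(start(gr), end(gr)))
  if (!is.null(mc$name) && !anyNA(mc$name)) gr2$tad_id <- as.character(mc$name)
  TADSet(gr2, style = style, provenance = provenance, binSize = binSize)
}

#' Write a TAD set to a BED file
#'
#' Coordinates round-trip bit-exactly through \code{readTads}.
#'
#' @param x A \code{TADSet}.
#' @param path Output BED path (BED4: the 4th column is the TAD id).
#' @return Invisibly, \code{path}.
#' @export
writeTads <- function(x, path) {
  gr <- tads(x)
  out <- GRanges(as.character(seqnames(gr)), IRanges(start(gr), end(gr)))
  out$name <- gr$tad_id
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read a peak set (e.g. CTCF ChIP-seq peaks or assembly gaps) from BED
#'
#' @param path BED3+ file.
#' @return A \code{GRanges} of peak intervals.
#' @export
readPeaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(width(gr) < 1L)) stop("peak with non-positive width")
  GRanges(as.character(seqnames(gr)), IRanges(start(gr), end(gr)))
}

#' Read an A/B compartment track from BED4
#'
#' @param path BED4 file whose name column is "A" or "B".
#' @return A \code{GRanges} with a \code{compartment} metadata column.
#' @export
readCompartments <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  lab <- as.character(mcols(gr)$name)
  if (is.null(lab) || anyNA(lab) || !all(lab %in% c("A", "B")))
    stop("compartment track labels must all be 'A' or 'B'")
  out <- GRanges(as.character(seqnames(gr)), IRanges(start(gr), end(gr)))
  out$compartment <- lab
  hits <- findOverlaps(out, minoverlap = 1L, drop.self = TRUE)
  if (length(hits))
    stop("compartment intervals must be non-overlapping within a chromosome")
  out
}

#' Read a gene x sample expression matrix (FPKM/RPKM) from TSV
#'
#' @param path TSV with a \code{gene_id} column followed by one numeric
#'   column per sample.
#' @return Numeric matrix with gene ids as row names.
#' @export
readExpression <- function(path) {
  df <- .readTsv(path, "gene_id", "expression matrix")
  ids <- as.character(df$gene_id)
  if (anyDuplicated(ids)) stop("duplicate gene_id in expression matrix")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  rownames(m) <- ids
  m
}

.readPairTsv <- function(path, what) {
  df <- .readTsv(path, c("gene_id_1", "gene_id_2"), what)
  df <- data.frame(gene_a = as.character(df$gene_id_1),
                   gene_b = as.character(df$gene_id_2),
                   stringsAsFactors = FALSE)
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]; df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp
  df[!duplicated(paste(df$gene_a, df$gene_b)), , drop = FALSE]
}

#' Assemble an AnnotationCorpus from TSV tables
#'
#' Any input may be omitted; the corresponding slot is left empty and the
#' metrics that need it return NA.
#'
#' @param goPath TSV (gene_id, term_id).
#' @param ontologyPath TSV (child_term, parent_term) rooted-DAG edge list.
#' @param pathwaysPath TSV (gene_id, pathway_id).
#' @param ppiPath TSV (gene_id_1, gene_id_2), pre-filtered to physical
#'   ("binding") interactions.
#' @param paralogsPath TSV (gene_id_1, gene_id_2).
#' @param maskPath TSV (gene_id) of genes to mask (e.g. olfactory).
#' @param constraintPath TSV (transcript_id, gene_id, score).
#' @return A validated \code{AnnotationCorpus}.
#' @export
readAnnotationCorpus <- function(goPath = NULL, ontologyPath = NULL,
                                 pathwaysPath = NULL, ppiPath = NULL,
                                 paralogsPath = NULL, maskPath = NULL,
                                 constraintPath = NULL) {
  go <- list()
  if (!is.null(goPath)) {
    df <- .readTsv(goPath, c("gene_id", "term_id"), "GO annotation")
    go <- lapply(split(as.character(df$term_id), as.character(df$gene_id)),
                 unique)
  }
  edges <- data.frame(child = character(), parent = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(ontologyPath)) {
    df <- .readTsv(ontologyPath, c("child_term", "parent_term"),
                   "ontology edges")
    edges <- data.frame(child = as.character(df$child_term),
                        parent = as.character(df$parent_term),
                        stringsAsFactors = FALSE)
  }
  pw <- list()
  if (!is.null(pathwaysPath)) {
    df <- .readTsv(pathwaysPath, c("gene_id", "pathway_id"), "pathways")
    pw <- lapply(split(as.character(df$pathway_id),
                       as.character(df$gene_id)), unique)
  }
  ppi <- data.frame(gene_a = character(), gene_b = character(),
                    stringsAsFactors = FALSE)
  if (!is.null(ppiPath)) ppi <- .readPairTsv(ppiPath, "PPI edges")
  par <- data.frame(gene_a = character(), gene_b = character(),
                    stringsAsFactors = FALSE)
  if (!is.null(paralogsPath)) par <- .readPairTsv(paralogsPath, "paralog pairs")
  mask <- character()
  if (!is.null(maskPath)) {
    df <- .readTsv(maskPath, "gene_id", "gene mask")
    mask <- unique(as.character(df$gene_id))
  }
  cons <- data.frame(transcript_id = character(), gene_id = character(),
                     score = numeric(), stringsAsFactors = FALSE)
  if (!is.null(constraintPath)) {
    df <- .readTsv(constraintPath, c("transcript_id", "gene_id", "score"),
                   "constraint")
    cons <- data.frame(transcript_id = as.character(df$transcript_id),
                       gene_id = as.character(df$gene_id),
                       score = .checkNumericColumn(df, "score", "constraint"),
                       stringsAsFactors = FALSE)
  }
  AnnotationCorpus(goAnnotations = go, ontologyEdges = edges, pathways = pw,
                   ppiEdges = ppi, paralogPairs = par, maskGenes = mask,
                   constraint = cons)
}

#' Construct an AnnotationCorpus from in-memory objects
#'
#' @param goAnnotations Named list: gene -> character vector of term ids.
#' @param ontologyEdges data.frame(child, parent).
#' @param pathways Named list: gene -> character vector of pathway ids.
#' @param ppiEdges data.frame(gene_a, gene_b).
#' @param paralogPairs data.frame(gene_a, gene_b).
#' @param maskGenes Character vector.
#' @param constraint data.frame(transcript_id, gene_id, score).
#' @return A validated \code{AnnotationCorpus}.
#' @export
AnnotationCorpus <- function(goAnnotations = list(),
                             ontologyEdges = data.frame(child = character(),
                                                        parent = character()),
                             pathways = list(),
                             ppiEdges = data.frame(gene_a = character(),
                                                   gene_b = character()),
                             paralogPairs = data.frame(gene_a = character(),
                                                       gene_b = character()),
                             maskGenes = character(),
                             constraint = data.frame(
                               transcript_id = character(),
                               gene_id = character(), score = numeric())) {
  new("AnnotationCorpus", goAnnotations = goAnnotations,
      ontologyEdges = ontologyEdges, pathways = pathways,
      ppiEdges = ppiEdges, paralogPairs = paralogPairs,
      maskGenes = maskGenes, constraint = constraint)
}

#' Drop TADs shorter than a minimum size
#'
#' Mirrors the small-domain input filter (e.g. removing partition-style
#' calls under 90 kb, a handful of Hi-C bins, which are unlikely to be
#' real domains).
#'
#' @param x A \code{TADSet}.
#' @param minBp Minimum retained width in bp (width = end - start in
#'   half-open terms).
#' @return A \code{TADSet}; the number removed is reported via message().
#' @export
filterMinSize <- function(x, minBp) {
  stopifnot(is(x, "TADSet"), minBp >= 0)
  gr <- tads(x)
  keep <- width(gr) >= minBp
  removed <- sum(!keep)
  if (removed) message(sprintf("filterMinSize: removed %d TAD(s) < %g bp",
                               removed, minBp))
  if (!any(keep)) warning("all TADs removed by the minimum-size filter")
  initialize(x, tads = gr[keep])
}

#' Remove records on named chromosomes
#'
#' Default removes the sex chromosomes, which are excluded from every
#' downstream analysis.
#'
#' @param x A \code{GenomeModel} or \code{TADSet}.
#' @param chroms Chromosome names to drop (default c("chrX", "chrY")).
#' @return Object of the same class without the listed chromosomes.
#' @export
setGeneric("excludeChromosomes",
           function(x, chroms = c("chrX", "chrY"))
             standardGeneric("excludeChromosomes"))

#' @rdname excludeChromosomes
#' @export
setMethod("excludeChromosomes", "GenomeModel", function(x, chroms) {
  gr <- genes(x)
  keepLv <- setdiff(seqlevels(gr), chroms)
  gr <- gr[!(as.character(seqnames(gr)) %in% chroms)]
  gr <- keepSeqlevels(gr, keepLv, pruning.mode = "coarse")
  initialize(x, genes = gr)
})

#' @rdname excludeChromosomes
#' @export
setMethod("excludeChromosomes", "TADSet", function(x, chroms) {
  gr <- tads(x)
  initialize(x, tads = gr[!(as.character(seqnames(gr)) %in% chroms)])
})

#' Remove masked genes from a GenomeModel or gene-pair table
#'
#' For pair tables, any pair touching a masked gene is dropped. Masking is
#' idempotent.
#'
#' @param x A \code{GenomeModel}, or a data.frame with \code{gene_a} /
#'   \code{gene_b} columns (a gene-pair table).
#' @param mask Character vector of gene ids to remove.
#' @return Object of the same type with masked genes removed.
#' @export
applyGeneMask <- function(x, mask) {
  mask <- as.character(mask)
  if (is(x, "GenomeModel")) {
    gr <- genes(x)
    return(initialize(x, genes = gr[!(gr$gene_id %in% mask)]))
  }
  if (is.data.frame(x) && all(c("gene_a", "gene_b") %in% names(x)))
    return(x[!(x$gene_a %in% mask | x$gene_b %in% mask), , drop = FALSE])
  stop("applyGeneMask: unsupported input type")
}
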