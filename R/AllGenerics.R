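# Accessor generics. Slot access stays behind these everywhere.

#' Extract the gene coordinates of a GenomeModel
#' @param x A \code{GenomeModel}.
#' @return A \code{GRanges} with a \code{gene_id} column.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname genes
#' @export
setMethod("genes", "GenomeModel", function(x) x@genes)

#' Chromosome lengths of a GenomeModel
#' @param x A \code{GenomeModel}.
#' @return Named numeric vector of chromosome lengths (bp).
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname chromSizes
#' @export
setMethod("chromSizes", "GenomeModel", function(x) seqlengths(x@genes))

#' TAD intervals of a TADSet
#' @param x A \code{TADSet}.
#' @return A \code{GRanges} with a \code{tad_id} column.
#' @export
setGeneric("tads", function(x) standardGeneric("tads"))

#' @rdname tads
#' @export
setMethod("tads", "TADSet", function(x) x@tads)

#' Style of a TADSet ("partition" or "overlapping")
#' @param x A \code{TADSet}.
#' @return Character scalar.
#' @export
setGeneric("tadStyle", function(x) standardGeneric("tadStyle"))

#' @rdname tadStyle
#' @export
setMethod("tadStyle", "TADSet", function(x) x@style)

#' Provenance of a TADSet
#' @param x A \code{TADSet}.
#' @return Character scalar (e.g. "real", "random_positional").
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname provenance
#' @export
setMethod("provenance", "TADSet", function(x) x@provenance)

#' Hi-C bin size of a TADSet (bp)
#' @param x A \code{TADSet}.
#' @return Numeric scalar.
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname binSize
#' @export
setMethod("binSize", "TADSet", function(x) x@binSize)

#' Sets of a NullEnsemble
#' @param x A \code{NullEnsemble}.
#' @return List of \code{TADSet} or \code{GenomeModel} objects.
#' @export
setGeneric("nullSets", function(x) standardGeneric("nullSets"))

#' @rdname nullSets
#' @export
setMethod("nullSets", "NullEnsemble", function(x) x@sets)

#' Per-set sub-seeds of a NullEnsemble
#' @param x A \code{NullEnsemble}.
#' @return Integer vector.
#' @export
setGeneric("setSeeds", function(x) standardGeneric("setSeeds"))

#' @rdname setSeeds
#' @export
setMethod("setSeeds", "NullEnsemble", function(x) x@seeds)

#' Per-set excluded-TAD counts of a NullEnsemble
#' @param x A \code{NullEnsemble}.
#' @return Integer vector.
#' @export
setGeneric("excludedCounts", function(x) standardGeneric("excludedCounts"))

#' @rdname excludedCounts
#' @export
setMethod("excludedCounts", "NullEnsemble", function(x) x@excluded)

#' Median p-value of a ComparisonResult
#' @param x A \code{ComparisonResult}.
#' @return Numeric scalar.
#' @export
setGeneric("medianP", function(x) standardGeneric("medianP"))

#' @rdname medianP
#' @export
setMethod("medianP", "ComparisonResult", function(x) x@medianP)

#' Median signed effect size r of a ComparisonResult
#' @param x A \code{ComparisonResult}.
#' @return Numeric scalar in [-1, 1].
#' @export
setGeneric("medianEffectSize", function(x) standardGeneric("medianEffectSize"))

#' @rdname medianEffectSize
#' @export
setMethod("medianEffectSize", "ComparisonResult",
          function(x) x@medianEffectSize)

#' Per-null-set p-values of a ComparisonResult
#' @param x A \code{ComparisonResult}.
#' @return Numeric vector, one p per null set.
#' @export
setGeneric("perSetPValues", function(x) standardGeneric("perSetPValues"))

#' @rdname perSetPValues
#' @export
setMethod("perSetPValues", "ComparisonResult", function(x) x@pValues)

#' Per-null-set signed effect sizes of a ComparisonResult
#' @param x A \code{ComparisonResult}.
#' @return Numeric vector, one r per null set.
#' @export
setGeneric("perSetEffectSizes",
           function(x) standardGeneric("perSetEffectSizes"))

#' @rdname perSetEffectSizes
#' @export
setMethod("perSetEffectSizes", "ComparisonResult", function(x) x@effectSizes)
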