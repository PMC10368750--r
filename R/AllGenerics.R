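#' Accessors for lncSieve containers
#'
#' Small accessor family for the S4 containers: gene spans, exons and
#' chromosome sizes of a \linkS4class{GeneAnnotation}; exon blocks and
#' flags of a \linkS4class{TranscriptMaps}; candidate table, stage
#' counts, cluster map and side channel of a \linkS4class{CascadeResult}.
#'
#' @param x an lncSieve container object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("geneExons", function(x) standardGeneric("geneExons"))
#' @rdname accessors
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))
#' @rdname accessors
#' @export
setGeneric("txExons", function(x) standardGeneric("txExons"))
#' @rdname accessors
#' @export
setGeneric("txFlags", function(x) standardGeneric("txFlags"))
#' @rdname accessors
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
#' @rdname accessors
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))
#' @rdname accessors
#' @export
setGeneric("clusterMap", function(x) standardGeneric("clusterMap"))
#' @rdname accessors
#' @export
setGeneric("sideChannel", function(x) standardGeneric("sideChannel"))

#' @rdname accessors
setMethod("genes", "GeneAnnotation", function(x) x@genes)
#' @rdname accessors
setMethod("geneExons", "GeneAnnotation", function(x) x@exons)
#' @rdname accessors
setMethod("chromSizes", "GeneAnnotation", function(x) {
  seqlengths(x@genes)
})
#' @rdname accessors
setMethod("txExons", "TranscriptMaps", function(x) x@exons)
#' @rdname accessors
setMethod("txFlags", "TranscriptMaps", function(x) x@flags)
#' @rdname accessors
setMethod("candidates", "CascadeResult", function(x) x@candidates)
#' @rdname accessors
setMethod("stageCounts", "CascadeResult", function(x) x@stageCounts)
#' @rdname accessors
setMethod("clusterMap", "CascadeResult", function(x) x@clusterMap)
#' @rdname accessors
setMethod("sideChannel", "CascadeResult", function(x) x@sideChannel)
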