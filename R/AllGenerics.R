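#' @rdname accessors
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname accessors
#' @export
setGeneric("mitoGenes", function(x) standardGeneric("mitoGenes"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("scaledValues", function(x) standardGeneric("scaledValues"))

#' @rdname accessors
#' @export
setGeneric("logValues", function(x) standardGeneric("logValues"))

#' @rdname leafLabels
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))

#' Divisive intelligent k-means clustering
#'
#' @param x a [NormalizedMatrix-class] (cells are clustered on scaled
#'   selected features) or a plain numeric matrix with observations in
#'   rows and features in columns.
#' @param params a [divikParams()] list.
#' @return a [ClusterTree-class].
#' @export
setGeneric("divik", function(x, params = divikParams()) standardGeneric("divik"))

#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname accessors
#' @export
setGeneric("ratioTable", function(x) standardGeneric("ratioTable"))
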