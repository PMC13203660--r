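#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor family used across the package: \code{rasterGrid} returns
#' the \linkS4class{RasterGrid} an object lives on, \code{cellValues} the
#' per-cell numeric payload, \code{nodataMask} the logical nodata mask,
#' \code{variableNames} the variable order of a stack-like object,
#' \code{criterionWeights} the named weight vector, \code{methodTag} the
#' producing-method tag, \code{classValues} the integer class matrix of a
#' classified map and \code{occurrenceCoords} the lon/lat matrix of an
#' occurrence set.
#'
#' @param x an object of one of the package's classes
#' @return see the individual descriptions above
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rasterGrid", function(x) standardGeneric("rasterGrid"))

#' @rdname accessors
#' @export
setGeneric("cellValues", function(x) standardGeneric("cellValues"))

#' @rdname accessors
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))

#' @rdname accessors
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' @rdname accessors
#' @export
setGeneric("criterionWeights", function(x) standardGeneric("criterionWeights"))

#' @rdname accessors
#' @export
setGeneric("methodTag", function(x) standardGeneric("methodTag"))

#' @rdname accessors
#' @export
setGeneric("classValues", function(x) standardGeneric("classValues"))

#' @rdname accessors
#' @export
setGeneric("occurrenceCoords", function(x) standardGeneric("occurrenceCoords"))

#' @rdname accessors
#' @export
setGeneric("consistencyRatio", function(x) standardGeneric("consistencyRatio"))
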