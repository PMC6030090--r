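#' Accessor generics
#'
#' Small accessor generics for the package's S4 result classes; see the class
#' pages for the meaning of each slot.
#'
#' @param x an object of the documented classes.
#' @name slopeCN-accessors
NULL

#' @rdname slopeCN-accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("chemistry", function(x) standardGeneric("chemistry"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("breakpoints", function(x) standardGeneric("breakpoints"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("segmentNames", function(x) standardGeneric("segmentNames"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("modelFamily", function(x) standardGeneric("modelFamily"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("r2", function(x) standardGeneric("r2"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("rmse", function(x) standardGeneric("rmse"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("nodesExplored", function(x) standardGeneric("nodesExplored"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("exhaustiveNodes", function(x) standardGeneric("exhaustiveNodes"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("noiseEquivalents", function(x) standardGeneric("noiseEquivalents"))

#' @rdname slopeCN-accessors
#' @export
setGeneric("cnGrid", function(x) standardGeneric("cnGrid"))
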