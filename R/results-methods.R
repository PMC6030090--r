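#' @rdname slopeCN-accessors
#' @export
setMethod("breakpoints", "SegmentScheme", function(x) x@breakpoints)

#' @rdname slopeCN-accessors
#' @export
setMethod("segmentNames", "SegmentScheme", function(x) x@segmentNames)

setMethod("show", "SegmentScheme", function(object) {
    bp <- object@breakpoints
    cat("SegmentScheme with", length(object@segmentNames), "segments:\n")
    for (i in seq_along(object@segmentNames))
        cat(sprintf("  %-5s %g-%g nm\n", object@segmentNames[i],
                    bp[i], bp[i + 1]))
})

#' @rdname slopeCN-accessors
#' @export
setMethod("modelFamily", "ModelFit", function(x) x@family)

#' @rdname slopeCN-accessors
#' @export
setMethod("r2", "ModelFit", function(x) x@r2)

#' @rdname slopeCN-accessors
#' @export
setMethod("rmse", "ModelFit", function(x) x@rmse)

#' @rdname slopeCN-accessors
#' @export
setMethod("pValue", "ModelFit", function(x) x@pValue)

#' @rdname slopeCN-accessors
#' @export
setMethod("isSignificant", "ModelFit", function(x) x@significant)

#' @describeIn ModelFit-class model parameters `c(a = , b = )`.
#' @param object a `ModelFit`.
#' @param ... unused.
#' @export
setMethod("coef", "ModelFit", function(object, ...)
    c(a = object@a, b = object@b))

#' Evaluate a fitted univariate model at new predictor values
#'
#' @param object a [ModelFit-class].
#' @param newx numeric predictor values on the scale the model was fitted with
#'   (the `x` of `fitFamily()`).
#' @param ... unused.
#' @return fitted response values.
#' @export
setMethod("predict", "ModelFit", function(object, newx, ...) {
    switch(object@family,
        linear      = object@a + object@b * newx,
        exponential = object@a * exp(object@b * newx),
        logarithmic = object@a + object@b * log(newx))
})

setMethod("show", "ModelFit", function(object) {
    eqn <- switch(object@family,
        linear      = sprintf("y = %.4g + %.4g x", object@a, object@b),
        exponential = sprintf("y = %.4g exp(%.4g x)", object@a, object@b),
        logarithmic = sprintf("y = %.4g + %.4g ln(x)", object@a, object@b))
    cat(sprintf("ModelFit [%s, %s]: %s\n", object@family, object@direction,
                eqn))
    cat(sprintf("  R2 = %.4f  RMSE = %.4f  p = %.3g%s  (n = %d)\n",
                object@r2, object@rmse, object@pValue,
                if (object@significant) "" else " (not significant)",
                object@n))
})

#' @rdname slopeCN-accessors
#' @export
setMethod("members", "SubsetResult", function(x) x@members)

#' @rdname slopeCN-accessors
#' @export
setMethod("r2", "SubsetResult", function(x) x@r2)

#' @rdname slopeCN-accessors
#' @export
setMethod("rmse", "SubsetResult", function(x) x@rmse)

#' @describeIn SubsetResult-class intercept and member slopes.
#' @param object a `SubsetResult`.
#' @param ... unused.
#' @export
setMethod("coef", "SubsetResult", function(object, ...) object@coefficients)

setMethod("show", "SubsetResult", function(object) {
    cat(sprintf("SubsetResult k = %d: {%s}\n", object@k,
                paste(object@members, collapse = ", ")))
    cat(sprintf("  RSS = %.6g  R2 = %.4f  RMSE = %.4f  (n = %d)\n",
                object@rss, object@r2, object@rmse, object@n))
})

#' @rdname slopeCN-accessors
#' @export
setMethod("nodesExplored", "SubsetPath", function(x) x@nodesExplored)

#' @rdname slopeCN-accessors
#' @export
setMethod("exhaustiveNodes", "SubsetPath", function(x) x@exhaustiveNodes)

#' Tabulate a subset-selection path
#'
#' @param path a [SubsetPath-class].
#' @return `data.frame` with one row per subset size: `k`, comma-separated
#'   `members`, `rss`, `r2`, `rmse`.
#' @export
pathTable <- function(path) {
    stopifnot(methods::is(path, "SubsetPath"))
    do.call(rbind, lapply(path@results, function(r)
        data.frame(k = r@k,
                   members = paste(r@members, collapse = ";"),
                   rss = r@rss, r2 = r@r2, rmse = r@rmse,
                   stringsAsFactors = FALSE)))
}

setMethod("show", "SubsetPath", function(object) {
    cat("SubsetPath over k = 1 ..", length(object@results), "\n")
    print(pathTable(object), row.names = FALSE)
    cat(sprintf("  nodes explored: %g of %g exhaustive\n",
                object@nodesExplored, object@exhaustiveNodes))
})

#' @rdname slopeCN-accessors
#' @export
setMethod("noiseEquivalents", "SensitivityCurve", function(x) x@ne)

#' @rdname slopeCN-accessors
#' @export
setMethod("cnGrid", "SensitivityCurve", function(x) x@cnGrid)

setMethod("show", "SensitivityCurve", function(object) {
    fin <- is.finite(object@ne)
    cat(sprintf("SensitivityCurve for '%s' (%s fit)\n", object@featureName,
                object@fit@family))
    if (any(fin))
        cat(sprintf("  NE dC/N over C/N %.3g-%.3g: %.4g-%.4g\n",
                    min(object@cnGrid), max(object@cnGrid),
                    min(object@ne[fin]), max(object@ne[fin])))
    if (any(!fin))
        cat("  ", sum(!fin), "grid points flagged infinite (zero derivative)\n")
})
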