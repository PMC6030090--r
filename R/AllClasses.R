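#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats coef cor lm lm.fit predict pt qt rnorm runif sd setNames
#' @importFrom utils combn read.csv write.csv
NULL

#' SpectralSet: a set of canopy reflectance spectra on a shared wavelength grid
#'
#' `SpectralSet` extends [SummarizedExperiment::SummarizedExperiment]. Rows are
#' wavelengths (in nm, strictly increasing, stored in `rowData(x)$wavelength_nm`),
#' columns are samples, and the single assay `"reflectance"` holds the
#' reflectance matrix. Sample chemistry (`species`, `LNC`, `LCC`, `CN`) lives in
#' `colData`. Whether the spectra have been mean-normalized is recorded in
#' `metadata(x)$normalized` and is enforced by the validity method
#' (column means equal to 1 within 1e-9).
#'
#' @section Units:
#' Wavelengths are physical nanometres; reflectance is dimensionless (raw
#' reflectance in \[0, 1\] or normalized reflectance with mean 1 per spectrum).
#' `LNC` and `LCC` are g per 100 g dry mass; `CN = LCC / LNC` is dimensionless.
#'
#' @name SpectralSet-class
#' @aliases SpectralSet-class
#' @exportClass SpectralSet
setClass("SpectralSet", contains = "SummarizedExperiment")

setValidity("SpectralSet", function(object) {
    msg <- character()
    rd <- SummarizedExperiment::rowData(object)
    if (!"wavelength_nm" %in% colnames(rd))
        return("rowData must contain a 'wavelength_nm' column")
    wl <- rd$wavelength_nm
    if (!is.numeric(wl) || anyNA(wl))
        msg <- c(msg, "'wavelength_nm' must be numeric and non-missing")
    else if (length(wl) > 1L && any(diff(wl) <= 0))
        msg <- c(msg, "wavelengths must be strictly increasing")
    if (!"reflectance" %in% SummarizedExperiment::assayNames(object))
        return("assay 'reflectance' is required")
    refl <- SummarizedExperiment::assay(object, "reflectance")
    if (!all(is.finite(refl)))
        msg <- c(msg, "reflectance values must be finite")
    else if (any(refl < 0))
        msg <- c(msg, "reflectance values must be non-negative")
    norm <- S4Vectors::metadata(object)$normalized
    if (isTRUE(norm) && ncol(refl) > 0L) {
        cm <- colMeans(refl)
        if (any(abs(cm - 1) > 1e-9))
            msg <- c(msg, "normalized spectra must have mean 1 (tolerance 1e-9)")
    }
    if (length(msg)) msg else TRUE
})

#' SegmentScheme: breakpoints defining the slope segments
#'
#' Ordered breakpoint wavelengths partitioning the working range into the named
#' segments over which per-segment slopes are fitted. The default scheme places
#' breakpoints at 400, 500, 550, 680, 760, 910, 960 and 1050 nm, the inflection
#' points between the major peaks and valleys of a cereal canopy spectrum,
#' yielding seven segments: `pb` (photosynthetic blue rise, 400–500), `ge`
#' (green edge, 500–550), `gprv` (green peak to red valley, 550–680), `re`
#' (red edge, 680–760), `nir` (760–910), `nir2` (910–960) and `nir3`
#' (960–1050).
#'
#' Segments are closed intervals sharing endpoints: a breakpoint band
#' contributes to both adjacent segment fits.
#'
#' @slot breakpoints numeric, strictly increasing wavelengths (nm).
#' @slot segmentNames character, one name per segment
#'   (`length(breakpoints) - 1`).
#' @name SegmentScheme-class
#' @aliases SegmentScheme-class
#' @exportClass SegmentScheme
setClass("SegmentScheme",
    representation(breakpoints = "numeric", segmentNames = "character"))

setValidity("SegmentScheme", function(object) {
    msg <- character()
    bp <- object@breakpoints
    if (length(bp) < 2L || anyNA(bp) || any(diff(bp) <= 0))
        msg <- c(msg, "breakpoints must be >= 2 strictly increasing wavelengths")
    if (length(object@segmentNames) != length(bp) - 1L)
        msg <- c(msg, "need exactly one segment name per interval")
    if (anyDuplicated(object@segmentNames))
        msg <- c(msg, "segment names must be unique")
    if (length(msg)) msg else TRUE
})

#' ModelFit: a fitted univariate functional relationship
#'
#' Holds one fitted model from the linear / exponential / logarithmic family
#' set: `linear` is `y = a + b x`, `exponential` is `y = a exp(b x)` (fitted by
#' OLS on `ln y`), `logarithmic` is `y = a + b ln(x)` (OLS on `ln x`). `r2` and
#' `rmse` are always evaluated on the original response scale so families are
#' comparable; `rmse` uses denominator `n`. `pValue` is the two-tailed
#' significance of the slope of the (possibly linearized) regression, and
#' `significant` flags `pValue < 0.01`. `direction` records which variable was
#' the predictor (`"feature->CN"` for estimation models, `"CN->feature"` for
#' sensitivity analysis).
#'
#' @slot family character, one of "linear", "exponential", "logarithmic".
#' @slot a,b numeric model parameters.
#' @slot r2 coefficient of determination on the original response scale.
#' @slot rmse root mean squared error, response units, denominator n.
#' @slot pValue two-tailed slope significance.
#' @slot significant logical, `pValue < 0.01`.
#' @slot n sample count.
#' @slot direction character label of the fit direction.
#' @name ModelFit-class
#' @aliases ModelFit-class
#' @exportClass ModelFit
setClass("ModelFit",
    representation(family = "character", a = "numeric", b = "numeric",
        r2 = "numeric", rmse = "numeric", pValue = "numeric",
        significant = "logical", n = "integer", direction = "character"))

setValidity("ModelFit", function(object) {
    msg <- character()
    if (!object@family %in% c("linear", "exponential", "logarithmic"))
        msg <- c(msg, "unknown model family")
    if (is.finite(object@r2) && object@r2 > 1 + 1e-9)
        msg <- c(msg, "r2 cannot exceed 1")
    if (is.finite(object@rmse) && object@rmse < 0)
        msg <- c(msg, "rmse must be non-negative")
    if (length(msg)) msg else TRUE
})

#' SubsetResult: one optimal feature subset with its least-squares fit
#'
#' @slot k subset size.
#' @slot members character, the k selected feature names (ascending candidate
#'   order).
#' @slot coefficients named numeric: intercept first, then one slope per
#'   member.
#' @slot rss residual sum of squares.
#' @slot r2 coefficient of determination.
#' @slot rmse root mean squared error (denominator n).
#' @slot n sample count.
#' @name SubsetResult-class
#' @aliases SubsetResult-class
#' @exportClass SubsetResult
setClass("SubsetResult",
    representation(k = "integer", members = "character",
        coefficients = "numeric", rss = "numeric", r2 = "numeric",
        rmse = "numeric", n = "integer"))

setValidity("SubsetResult", function(object) {
    msg <- character()
    if (length(object@members) != object@k)
        msg <- c(msg, "members must contain exactly k names")
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must be distinct")
    if (length(object@coefficients) != object@k + 1L)
        msg <- c(msg, "coefficients must be intercept + one slope per member")
    if (length(msg)) msg else TRUE
})

#' SubsetPath: per-size optimal subsets from branch-and-bound selection
#'
#' Results of [subsetPath()]: the globally optimal subset for each size
#' `k = 1 ... kMax`, plus node counts demonstrating how much of the subset
#' lattice the branch-and-bound search actually evaluated relative to
#' exhaustive enumeration. Along the path, RSS is non-increasing and R² is
#' non-decreasing in k (nested optimality).
#'
#' @slot results list of [SubsetResult-class], element k is the size-k optimum.
#' @slot nodesExplored number of least-squares evaluations performed.
#' @slot exhaustiveNodes sum over k of choose(p, k), the exhaustive count.
#' @name SubsetPath-class
#' @aliases SubsetPath-class
#' @exportClass SubsetPath
setClass("SubsetPath",
    representation(results = "list", nodesExplored = "numeric",
        exhaustiveNodes = "numeric"))

#' SensitivityCurve: noise-equivalent change in C/N along a C/N grid
#'
#' For a spectral feature SF fitted as a function of C/N, the noise-equivalent
#' change NE dC/N at a C/N value is RMSE(SF vs C/N) divided by the absolute
#' analytic derivative |d SF / d C/N| of the fitted family. A lower NE means a
#' smaller change in C/N is resolvable above the fit residual noise, i.e.
#' higher local sensitivity. Grid points where the derivative vanishes carry
#' `Inf` (flagged, not an error).
#'
#' @slot featureName feature the curve describes.
#' @slot cnGrid C/N evaluation grid.
#' @slot ne noise-equivalent dC/N at each grid point.
#' @slot fit the [ModelFit-class] (direction CN->feature) behind the curve.
#' @name SensitivityCurve-class
#' @aliases SensitivityCurve-class
#' @exportClass SensitivityCurve
setClass("SensitivityCurve",
    representation(featureName = "character", cnGrid = "numeric",
        ne = "numeric", fit = "ModelFit"))

setValidity("SensitivityCurve", function(object) {
    if (length(object@cnGrid) != length(object@ne))
        return("cnGrid and ne must have equal length")
    if (any(object@ne[is.finite(object@ne)] < 0))
        return("noise equivalents must be positive")
    TRUE
})
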