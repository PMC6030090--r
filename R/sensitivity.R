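#' Noise-equivalent change in C/N for one feature
#'
#' Quantifies how finely a spectral feature can resolve C/N: the feature SF is
#' fitted as a function of C/N with [bestFit()] (direction CN -> feature), and
#' the noise equivalent at a C/N value is
#' `NE dC/N = RMSE(SF vs C/N) / |d SF / d C/N|`, the fit's residual scatter
#' divided by the local slope of the fitted curve. The derivative is taken
#' analytically from the fitted family (linear: `b`; exponential:
#' `a b exp(b CN)`; logarithmic: `b / CN`). Lower NE means higher local
#' sensitivity; because rescaling the feature by a constant scales RMSE and
#' derivative alike, NE is invariant to affine rescaling of the feature and
#' curves of different features are directly comparable.
#'
#' @param featureValues feature values per sample.
#' @param cnValues observed C/N per sample (positive, >= 3 samples).
#' @param cnGrid C/N values at which to evaluate NE; default 60 evenly spaced
#'   points over the observed C/N range.
#' @param featureName label stored in the curve.
#' @return a [SensitivityCurve-class]. Grid points with zero derivative carry
#'   `Inf` (flagged, not an error).
#' @export
noiseEquivalent <- function(featureValues, cnValues, cnGrid = NULL,
                            featureName = "feature") {
    if (length(featureValues) != length(cnValues))
        stop("feature and C/N vectors must have equal length", call. = FALSE)
    if (any(cnValues <= 0))
        stop("C/N values must be positive", call. = FALSE)
    if (is.null(cnGrid))
        cnGrid <- seq(min(cnValues), max(cnValues), length.out = 60)
    fit <- bestFit(cnValues, featureValues, direction = "CN->feature")
    dv <- switch(fit@family,
        linear      = rep(fit@b, length(cnGrid)),
        exponential = fit@a * fit@b * exp(fit@b * cnGrid),
        logarithmic = fit@b / cnGrid)
    ne <- ifelse(dv == 0, Inf, fit@rmse / abs(dv))
    methods::new("SensitivityCurve", featureName = featureName,
                 cnGrid = as.numeric(cnGrid), ne = as.numeric(ne), fit = fit)
}

#' Compare the sensitivity of several features on a shared C/N grid
#'
#' One [noiseEquivalent()] curve per feature, plus the crossing points between
#' every pair of curves (C/N values where the more sensitive feature changes),
#' located by linear interpolation between grid points where the NE difference
#' changes sign.
#'
#' @param table feature table with a `CN` column (e.g. from
#'   [buildFeatureTable()]).
#' @param featureNames which feature columns to compare.
#' @param cnGrid shared C/N grid; default 60 points over the table's C/N
#'   range.
#' @return list with `curves` (named list of [SensitivityCurve-class]) and
#'   `crossings` (`data.frame` with `feature1`, `feature2`, `CN`).
#' @export
compareSensitivity <- function(table, featureNames, cnGrid = NULL) {
    missing <- setdiff(featureNames, colnames(table))
    if (length(missing))
        stop("feature(s) not in table: ", paste(missing, collapse = ", "),
             call. = FALSE)
    if (is.null(cnGrid))
        cnGrid <- seq(min(table$CN), max(table$CN), length.out = 60)
    curves <- lapply(featureNames, function(f)
        noiseEquivalent(table[[f]], table$CN, cnGrid, featureName = f))
    names(curves) <- featureNames
    crossings <- data.frame(feature1 = character(), feature2 = character(),
                            CN = numeric(), stringsAsFactors = FALSE)
    if (length(featureNames) > 1L) {
        for (i in seq_len(length(featureNames) - 1L)) {
            for (j in (i + 1L):length(featureNames)) {
                d <- curves[[i]]@ne - curves[[j]]@ne
                fin <- is.finite(d)
                sgn <- sign(d)
                for (g in which(fin[-length(d)] & fin[-1])) {
                    if (sgn[g] != 0 && sgn[g + 1] != 0 &&
                        sgn[g] != sgn[g + 1]) {
                        frac <- d[g] / (d[g] - d[g + 1])
                        crossings <- rbind(crossings, data.frame(
                            feature1 = featureNames[i],
                            feature2 = featureNames[j],
                            CN = cnGrid[g] + frac * (cnGrid[g + 1] - cnGrid[g]),
                            stringsAsFactors = FALSE))
                    }
                }
            }
        }
    }
    list(curves = curves, crossings = crossings)
}
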