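#' Preprocessing configuration
#'
#' Parameters of the preprocessing chain applied to raw canopy reflectance:
#' truncation to the working wavelength range, centered moving-average
#' smoothing, and mean normalization. The defaults reproduce the standard
#' chain for field spectrometer data: reflectance below 400 nm is discarded as
#' noise-dominated, spectra are smoothed with a five-band average, and each
#' curve is divided by its own mean so that illumination differences between
#' measurements cancel.
#'
#' @param minWavelength,maxWavelength working range bounds in nm (inclusive).
#' @param smoothWindow odd moving-average width in bands.
#' @param normalize divide each spectrum by its mean?
#' @return a list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(minWavelength = 400, maxWavelength = 1050,
                             smoothWindow = 5, normalize = TRUE) {
    if (minWavelength >= maxWavelength)
        stop("minWavelength must be below maxWavelength", call. = FALSE)
    if (smoothWindow < 1 || smoothWindow %% 2 != 1)
        stop("smoothWindow must be a positive odd integer", call. = FALSE)
    structure(list(minWavelength = minWavelength,
                   maxWavelength = maxWavelength,
                   smoothWindow = as.integer(smoothWindow),
                   normalize = isTRUE(normalize)),
              class = "PreprocessConfig")
}

#' Truncate spectra to a wavelength range
#'
#' Restricts every spectrum to the inclusive range
#' `[minWavelength, maxWavelength]`; band order is preserved.
#'
#' @param x a [SpectralSet-class].
#' @param minWavelength,maxWavelength range bounds in nm.
#' @return the truncated `SpectralSet`.
#' @export
truncateSpectra <- function(x, minWavelength = 400, maxWavelength = 1050) {
    stopifnot(methods::is(x, "SpectralSet"))
    keep <- wavelengths(x) >= minWavelength & wavelengths(x) <= maxWavelength
    if (sum(keep) < 2L)
        stop("fewer than 2 bands fall inside [", minWavelength, ", ",
             maxWavelength, "] nm", call. = FALSE)
    SpectralSet(reflectance(x)[keep, , drop = FALSE], wavelengths(x)[keep],
                sampleData = SummarizedExperiment::colData(x),
                normalized = FALSE)
}

#' Smooth spectra with a centered moving average
#'
#' A centered moving average of odd width `window` over each reflectance
#' column; the wavelength grid is unchanged. At the spectrum ends the window
#' is truncated to the available neighbours (no padding or reflection), so the
#' band count is preserved.
#'
#' @param x a [SpectralSet-class].
#' @param window odd window width in bands; must not exceed the band count.
#' @return the smoothed `SpectralSet` (normalized flag cleared).
#' @export
smoothSpectra <- function(x, window = 5) {
    stopifnot(methods::is(x, "SpectralSet"))
    n <- nrow(x)
    if (window %% 2 != 1 || window < 1)
        stop("smoothing window must be a positive odd integer", call. = FALSE)
    if (window > n)
        stop("smoothing window (", window, ") exceeds band count (", n, ")",
             call. = FALSE)
    mat <- reflectance(x)
    h <- (window - 1L) / 2L
    idx <- seq_len(n)
    lo <- pmax(1L, idx - h)
    hi <- pmin(n, idx + h)
    cs <- apply(mat, 2, cumsum)
    cs <- rbind(0, cs)                     # cs[i+1] = sum of first i values
    sm <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
        (hi - lo + 1L)
    dimnames(sm) <- dimnames(mat)
    SpectralSet(sm, wavelengths(x),
                sampleData = SummarizedExperiment::colData(x),
                normalized = FALSE)
}

#' Mean-normalize spectra
#'
#' Divides each spectrum by its mean reflectance over all retained bands, so
#' every normalized spectrum has mean exactly 1. Because a multiplicative
#' illumination factor scales both numerator and denominator, normalized
#' spectra are invariant to illumination differences. Normalization is
#' idempotent.
#'
#' @param x a [SpectralSet-class]; every spectrum must have positive mean.
#' @return the normalized `SpectralSet` (`isNormalized(x)` becomes `TRUE`).
#' @export
normalizeSpectra <- function(x) {
    stopifnot(methods::is(x, "SpectralSet"))
    mat <- reflectance(x)
    cm <- colMeans(mat)
    if (any(cm <= 0))
        stop("spectrum '", colnames(mat)[which(cm <= 0)[1]],
             "' has non-positive mean reflectance", call. = FALSE)
    SpectralSet(sweep(mat, 2, cm, "/"), wavelengths(x),
                sampleData = SummarizedExperiment::colData(x),
                normalized = TRUE)
}

#' Run the full preprocessing chain
#'
#' Applies, in this exact order: truncation to the working range, moving-
#' average smoothing, and (unless disabled) mean normalization.
#'
#' @param x a [SpectralSet-class] of raw reflectance.
#' @param config a [preprocessConfig()] list.
#' @return the preprocessed `SpectralSet`.
#' @examples
#' set.seed(1)
#' raw <- generateDataset(generatorConfig(nSamples = 3, seed = 1))
#' pp <- preprocessSpectra(raw)
#' colMeans(reflectance(pp))          # all 1
#' @export
preprocessSpectra <- function(x, config = preprocessConfig()) {
    out <- truncateSpectra(x, config$minWavelength, config$maxWavelength)
    out <- smoothSpectra(out, config$smoothWindow)
    if (config$normalize) out <- normalizeSpectra(out)
    out
}
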