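#' Construct a segment scheme
#'
#' @param breakpoints strictly increasing breakpoint wavelengths (nm).
#' @param segmentNames one name per segment (`length(breakpoints) - 1`).
#' @return a [SegmentScheme-class].
#' @examples
#' segmentScheme()   # the default seven-segment scheme
#' @export
segmentScheme <- function(breakpoints = c(400, 500, 550, 680, 760, 910, 960,
                                          1050),
                          segmentNames = c("pb", "ge", "gprv", "re", "nir",
                                           "nir2", "nir3")) {
    methods::new("SegmentScheme", breakpoints = as.numeric(breakpoints),
                 segmentNames = segmentNames)
}

## the nine combined features (a, b) of (K_a + K_b)/(2 K_re), fixed order
.combinedPairs <- list(
    c("ge", "gprv"), c("ge", "nir"), c("ge", "nir2"), c("ge", "nir3"),
    c("pb", "ge"), c("pb", "gprv"), c("pb", "nir"), c("pb", "nir2"),
    c("pb", "nir3"))

#' Names of the 22 slope features in canonical order
#'
#' Singles first (scheme order), then the six ratios `K_x/K_re`, then the nine
#' combined features `(K_a + K_b)/(2 K_re)`.
#'
#' @param scheme a [SegmentScheme-class] (default scheme assumed for the ratio
#'   / combined block, which requires the standard segment names).
#' @return character vector of 22 feature names.
#' @export
slopeFeatureNames <- function(scheme = segmentScheme()) {
    sn <- segmentNames(scheme)
    singles <- paste0("K_", sn)
    others <- setdiff(sn, "re")
    ratios <- paste0("K_", others, "_over_K_re")
    combined <- vapply(.combinedPairs, function(p)
        paste0("K_", p[1], "_plus_K_", p[2], "_over_2K_re"), character(1))
    c(singles, ratios, combined)
}

#' Fit one segment slope by ordinary least squares
#'
#' Fits `Nr = k * lambda + b` over every band in the inclusive wavelength
#' range, wavelength (nm) as the independent variable. The slope `k` is the
#' segment's slope feature, in normalized-reflectance per nm.
#'
#' @param wavelength,reflectance numeric vectors of equal length (one
#'   spectrum), wavelengths strictly increasing.
#' @param wlLo,wlHi inclusive segment bounds (nm).
#' @return list with `slope`, `intercept`, `nBands`.
#' @examples
#' wl <- seq(400, 500, by = 25)
#' fitSegmentSlope(wl, 0.001 * wl + 0.05, 400, 500)$slope   # exactly 0.001
#' @export
fitSegmentSlope <- function(wavelength, reflectance, wlLo, wlHi) {
    stopifnot(length(wavelength) == length(reflectance))
    sel <- wavelength >= wlLo & wavelength <= wlHi
    if (sum(sel) < 2L)
        stop("fewer than 2 bands in segment [", wlLo, ", ", wlHi, "] nm",
             call. = FALSE)
    fit <- lm.fit(cbind(1, wavelength[sel]), reflectance[sel])
    list(slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]),
         nBands = sum(sel))
}

#' Extract the single segment slopes of one spectrum
#'
#' One OLS slope per segment of the scheme. Segment intervals are closed on
#' both ends, so a breakpoint band contributes to both adjacent fits (the
#' segments share their vertices).
#'
#' @param wavelength,reflectance one normalized spectrum.
#' @param scheme a [SegmentScheme-class]; the spectrum must cover its full
#'   breakpoint range.
#' @return named numeric vector of slopes (`K_<segment>`).
#' @export
extractSingleSlopes <- function(wavelength, reflectance,
                                scheme = segmentScheme()) {
    bp <- breakpoints(scheme)
    if (min(wavelength) > min(bp) || max(wavelength) < max(bp))
        stop("spectrum (", min(wavelength), "-", max(wavelength),
             " nm) does not cover the segment scheme (", min(bp), "-",
             max(bp), " nm)", call. = FALSE)
    sn <- segmentNames(scheme)
    slopes <- vapply(seq_along(sn), function(i)
        fitSegmentSlope(wavelength, reflectance, bp[i], bp[i + 1])$slope,
        numeric(1))
    setNames(slopes, paste0("K_", sn))
}

#' Extract the full 22-feature slope set of one spectrum
#'
#' Computes the seven single slopes, the six ratios `K_x / K_re`, and the nine
#' combined features `(K_a + K_b) / (2 K_re)`. The red-edge slope `K_re` is
#' the shared denominator; for green vegetation it is strongly positive, so a
#' near-zero `K_re` (e.g. a flat spectrum) signals a degenerate input and is
#' an error.
#'
#' @inheritParams extractSingleSlopes
#' @param sampleId label used in error messages.
#' @param combinedPairs optional list of custom `c(a, b)` segment-name pairs
#'   for additional combined features; defaults to the canonical nine.
#' @return named numeric vector of 22 features (more if custom pairs are
#'   given), in the order of [slopeFeatureNames()].
#' @export
extractFeatureSet <- function(wavelength, reflectance,
                              scheme = segmentScheme(),
                              sampleId = "spectrum",
                              combinedPairs = NULL) {
    singles <- extractSingleSlopes(wavelength, reflectance, scheme)
    kre <- singles[["K_re"]]
    if (abs(kre) < 1e-15)
        stop("degenerate red-edge slope (|K_re| < 1e-15) for sample '",
             sampleId, "'", call. = FALSE)
    sn <- segmentNames(scheme)
    others <- setdiff(sn, "re")
    ratios <- setNames(singles[paste0("K_", others)] / kre,
                       paste0("K_", others, "_over_K_re"))
    pairs <- if (is.null(combinedPairs)) .combinedPairs else combinedPairs
    combined <- vapply(pairs, function(p)
        (singles[[paste0("K_", p[1])]] + singles[[paste0("K_", p[2])]]) /
            (2 * kre), numeric(1))
    names(combined) <- vapply(pairs, function(p)
        paste0("K_", p[1], "_plus_K_", p[2], "_over_2K_re"), character(1))
    c(singles, ratios, combined)
}

#' Build the samples-by-features slope table of a dataset
#'
#' Applies [extractFeatureSet()] to every preprocessed spectrum and joins the
#' result with the observed C/N. Column order is deterministic: `sample_id`,
#' `CN`, then the 22 features of [slopeFeatureNames()].
#'
#' @param x a normalized [SpectralSet-class] with `CN` in its chemistry.
#' @param scheme a [SegmentScheme-class].
#' @return `data.frame`, one row per sample.
#' @export
buildFeatureTable <- function(x, scheme = segmentScheme()) {
    stopifnot(methods::is(x, "SpectralSet"))
    if (!isNormalized(x))
        stop("slope features are defined on normalized spectra; run ",
             "preprocessSpectra() first", call. = FALSE)
    wl <- wavelengths(x)
    mat <- reflectance(x)
    feats <- t(vapply(colnames(mat), function(id)
        extractFeatureSet(wl, mat[, id], scheme, sampleId = id),
        numeric(length(slopeFeatureNames(scheme)))))
    chem <- chemistry(x)
    cn <- if ("CN" %in% colnames(chem)) chem$CN else rep(NA_real_, nrow(chem))
    out <- data.frame(sample_id = colnames(mat), CN = cn,
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(feats))
}
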