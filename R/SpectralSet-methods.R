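#' Construct a SpectralSet
#'
#' Assemble a reflectance matrix and wavelength grid (optionally with sample
#' chemistry) into a [SpectralSet-class].
#'
#' @param reflectance numeric matrix, wavelengths in rows and samples in
#'   columns; column names are sample ids.
#' @param wavelength numeric vector of strictly increasing wavelengths (nm),
#'   one per row of `reflectance`.
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample metadata
#'   (rows matched to the columns of `reflectance`).
#' @param normalized logical flag: have the spectra been mean-normalized?
#' @return a `SpectralSet`.
#' @examples
#' wl <- 400:1050
#' refl <- cbind(A = seq(0.05, 0.5, length.out = length(wl)))
#' s <- SpectralSet(refl, wl)
#' wavelengths(s)[1:3]
#' @export
SpectralSet <- function(reflectance, wavelength, sampleData = NULL,
                        normalized = FALSE) {
    reflectance <- as.matrix(reflectance)
    if (is.null(colnames(reflectance)))
        colnames(reflectance) <- paste0("S", seq_len(ncol(reflectance)))
    if (nrow(reflectance) != length(wavelength))
        stop("'wavelength' must have one entry per row of 'reflectance'",
             call. = FALSE)
    if (is.null(sampleData)) {
        sampleData <- S4Vectors::DataFrame(row.names = colnames(reflectance))
    } else {
        sampleData <- S4Vectors::DataFrame(sampleData)
        rownames(sampleData) <- colnames(reflectance)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(reflectance = reflectance),
        rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelength)),
        colData = sampleData)
    out <- methods::new("SpectralSet", se)
    S4Vectors::metadata(out)$normalized <- isTRUE(normalized)
    methods::validObject(out)
    out
}

#' @rdname slopeCN-accessors
#' @export
setMethod("wavelengths", "SpectralSet", function(x)
    SummarizedExperiment::rowData(x)$wavelength_nm)

#' @rdname slopeCN-accessors
#' @export
setMethod("reflectance", "SpectralSet", function(x)
    SummarizedExperiment::assay(x, "reflectance"))

#' @rdname slopeCN-accessors
#' @export
setMethod("isNormalized", "SpectralSet", function(x)
    isTRUE(S4Vectors::metadata(x)$normalized))

#' @rdname slopeCN-accessors
#' @export
setMethod("chemistry", "SpectralSet", function(x) {
    cd <- SummarizedExperiment::colData(x)
    cbind(data.frame(sample_id = colnames(x), stringsAsFactors = FALSE),
          as.data.frame(cd, optional = TRUE))
})

#' Retrieve one spectrum as a data.frame
#'
#' @param x a [SpectralSet-class].
#' @param sampleId sample identifier (a column name of `x`).
#' @return a `data.frame` with columns `wavelength_nm` and `reflectance`.
#' @export
getSpectrum <- function(x, sampleId) {
    stopifnot(methods::is(x, "SpectralSet"))
    if (!sampleId %in% colnames(x))
        stop("sample '", sampleId, "' not found", call. = FALSE)
    data.frame(wavelength_nm = wavelengths(x),
               reflectance = reflectance(x)[, sampleId])
}

setMethod("show", "SpectralSet", function(object) {
    wl <- wavelengths(object)
    cat("SpectralSet with", ncol(object), "spectra x", nrow(object),
        "bands\n")
    if (length(wl))
        cat("  wavelength range:", min(wl), "-", max(wl), "nm\n")
    cat("  normalized:", isNormalized(object), "\n")
    cd <- SummarizedExperiment::colData(object)
    if (ncol(cd))
        cat("  sample data:", paste(colnames(cd), collapse = ", "), "\n")
})
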