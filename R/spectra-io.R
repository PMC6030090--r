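#' Read a spectral library from CSV
#'
#' Two layouts are supported. `wide`: first column `wavelength_nm`, one column
#' of reflectance per sample (header row gives sample ids). `long`: columns
#' `sample_id`, `wavelength_nm`, `reflectance`, in any row order. Rows are
#' sorted by wavelength per sample; duplicated wavelengths within a sample and
#' non-numeric cells are rejected with an error naming the offending
#' row/column. All samples must share one wavelength grid.
#'
#' @param path path to the CSV file.
#' @param layout `"wide"` or `"long"`.
#' @return a [SpectralSet-class] (no chemistry attached; see [joinDataset()]).
#' @seealso [writeSpectra()], [readSamples()]
#' @export
readSpectra <- function(path, layout = c("wide", "long")) {
    layout <- match.arg(layout)
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0L || ncol(df) == 0L)
        stop("empty spectral file: ", path, call. = FALSE)
    if (layout == "wide") {
        if (colnames(df)[1] != "wavelength_nm")
            stop("wide layout requires first column 'wavelength_nm', found '",
                 colnames(df)[1], "'", call. = FALSE)
        if (ncol(df) < 2L)
            stop("wide layout needs at least one sample column", call. = FALSE)
        for (j in seq_len(ncol(df))) {
            v <- df[[j]]
            if (!is.numeric(v)) {
                bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
                stop("non-numeric value in column '", colnames(df)[j],
                     "', data row ", if (is.na(bad)) "?" else bad,
                     call. = FALSE)
            }
            if (anyNA(v))
                stop("missing value in column '", colnames(df)[j],
                     "', data row ", which(is.na(v))[1], call. = FALSE)
        }
        ord <- order(df$wavelength_nm)
        df <- df[ord, , drop = FALSE]
        wl <- df$wavelength_nm
        if (anyDuplicated(wl))
            stop("duplicated wavelength ", wl[which(duplicated(wl))[1]],
                 " nm in spectral grid", call. = FALSE)
        mat <- as.matrix(df[, -1, drop = FALSE])
        rownames(mat) <- NULL
        return(SpectralSet(mat, wl))
    }
    ## long layout
    need <- c("sample_id", "wavelength_nm", "reflectance")
    if (!all(need %in% colnames(df)))
        stop("long layout requires columns ", paste(need, collapse = ", "),
             call. = FALSE)
    for (cn in c("wavelength_nm", "reflectance")) {
        if (!is.numeric(df[[cn]]) || anyNA(df[[cn]]))
            stop("non-numeric or missing value in column '", cn, "', data row ",
                 which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1],
                 call. = FALSE)
    }
    ids <- unique(as.character(df$sample_id))
    pieces <- lapply(ids, function(id) {
        sub <- df[df$sample_id == id, , drop = FALSE]
        sub <- sub[order(sub$wavelength_nm), , drop = FALSE]
        if (anyDuplicated(sub$wavelength_nm))
            stop("duplicated wavelength ",
                 sub$wavelength_nm[which(duplicated(sub$wavelength_nm))[1]],
                 " nm for sample '", id, "'", call. = FALSE)
        sub
    })
    wl <- pieces[[1]]$wavelength_nm
    for (p in pieces)
        if (length(p$wavelength_nm) != length(wl) ||
            any(p$wavelength_nm != wl))
            stop("wavelength grid mismatch: sample '", p$sample_id[1],
                 "' is not on the shared grid", call. = FALSE)
    mat <- vapply(pieces, function(p) p$reflectance, numeric(length(wl)))
    colnames(mat) <- ids
    SpectralSet(mat, wl)
}

#' Write a spectral library to CSV
#'
#' Inverse of [readSpectra()]; numbers are serialized with 15 significant
#' digits so a write/read round trip reproduces reflectance to better than
#' 1e-12.
#'
#' @param x a [SpectralSet-class].
#' @param path output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(x, path, layout = c("wide", "long")) {
    layout <- match.arg(layout)
    stopifnot(methods::is(x, "SpectralSet"))
    wl <- wavelengths(x)
    mat <- reflectance(x)
    if (layout == "wide") {
        out <- data.frame(wavelength_nm = .fmtNum(wl), check.names = FALSE,
                          stringsAsFactors = FALSE)
        for (id in colnames(mat)) out[[id]] <- .fmtNum(mat[, id])
    } else {
        out <- data.frame(
            sample_id = rep(colnames(mat), each = length(wl)),
            wavelength_nm = .fmtNum(rep(wl, times = ncol(mat))),
            reflectance = .fmtNum(as.vector(mat)),
            stringsAsFactors = FALSE)
    }
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

.fmtNum <- function(x) formatC(x, digits = 15, format = "g")

#' Read a sample chemistry table from CSV
#'
#' The CSV must have a header with `sample_id` and at least one of `CN` or the
#' pair `LNC`, `LCC` (a `species` column is optional; absent values may be
#' empty cells). C/N is the ratio of leaf carbon to leaf nitrogen
#' concentration, so when `CN` is absent it is filled as `LCC / LNC`; when all
#' three are present their consistency is checked to 1e-6 relative tolerance.
#'
#' @param path path to the CSV file.
#' @return `data.frame` with columns `sample_id`, `species`, `LNC`, `LCC`,
#'   `CN` (NA where absent).
#' @export
readSamples <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(df))
        stop("samples CSV requires a 'sample_id' column", call. = FALSE)
    if (!"species" %in% colnames(df)) df$species <- "other"
    df$species <- as.character(df$species)
    bad <- !df$species %in% c("wheat", "barley", "other")
    if (any(bad))
        stop("unknown species '", df$species[which(bad)[1]], "' in row ",
             which(bad)[1], call. = FALSE)
    for (cn in c("LNC", "LCC", "CN")) {
        if (!cn %in% colnames(df)) df[[cn]] <- NA_real_
        df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
    }
    for (i in seq_len(nrow(df))) {
        lnc <- df$LNC[i]; lcc <- df$LCC[i]; cnv <- df$CN[i]
        hasPair <- !is.na(lnc) && !is.na(lcc)
        if (is.na(cnv) && !hasPair)
            stop("row ", i, " ('", df$sample_id[i],
                 "'): need CN or both LNC and LCC", call. = FALSE)
        if (any(c(lnc, lcc, cnv) <= 0, na.rm = TRUE))
            stop("row ", i, " ('", df$sample_id[i],
                 "'): LNC, LCC and CN must be positive", call. = FALSE)
        if (is.na(cnv) && hasPair) {
            df$CN[i] <- lcc / lnc
        } else if (!is.na(cnv) && hasPair) {
            if (abs(cnv - lcc / lnc) > 1e-6 * abs(cnv))
                stop("row ", i, " ('", df$sample_id[i], "'): CN = ", cnv,
                     " inconsistent with LCC/LNC = ",
                     format(lcc / lnc, digits = 8), call. = FALSE)
        }
    }
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample_id: ",
             df$sample_id[which(duplicated(df$sample_id))[1]], call. = FALSE)
    df[, c("sample_id", "species", "LNC", "LCC", "CN")]
}

#' Join spectra with sample chemistry into one dataset
#'
#' Inner join on sample id; ids present on only one side are dropped with a
#' warning listing them. When `spectra` is a list of [SpectralSet-class]
#' objects they are combined first, erroring if wavelength grids differ.
#'
#' @param spectra a `SpectralSet` or a list of them (shared grid required).
#' @param samples `data.frame` from [readSamples()] (or equivalent, keyed by
#'   `sample_id`).
#' @return a `SpectralSet` whose `colData` carries `species`, `LNC`, `LCC`,
#'   `CN`.
#' @export
joinDataset <- function(spectra, samples) {
    if (is.list(spectra) && !methods::is(spectra, "SpectralSet")) {
        wl <- wavelengths(spectra[[1]])
        for (s in spectra[-1])
            if (length(wavelengths(s)) != length(wl) ||
                any(wavelengths(s) != wl))
                stop("wavelength grid mismatch between spectral sets",
                     call. = FALSE)
        mat <- do.call(cbind, lapply(spectra, reflectance))
        norm <- all(vapply(spectra, isNormalized, logical(1)))
        spectra <- SpectralSet(mat, wl, normalized = norm)
    }
    stopifnot(methods::is(spectra, "SpectralSet"))
    samples <- as.data.frame(samples)
    ids <- intersect(colnames(spectra), samples$sample_id)
    if (length(ids) == 0L)
        stop("no sample ids shared between spectra and chemistry table",
             call. = FALSE)
    dropSpec <- setdiff(colnames(spectra), ids)
    dropSamp <- setdiff(samples$sample_id, ids)
    if (length(dropSpec) || length(dropSamp))
        warning("dropped ids without a match - spectra: {",
                paste(dropSpec, collapse = ", "), "}; samples: {",
                paste(dropSamp, collapse = ", "), "}", call. = FALSE)
    ids <- colnames(spectra)[colnames(spectra) %in% ids]   # keep spectra order
    rows <- match(ids, samples$sample_id)
    cd <- samples[rows, setdiff(colnames(samples), "sample_id"), drop = FALSE]
    SpectralSet(reflectance(spectra)[, ids, drop = FALSE], wavelengths(spectra),
                sampleData = cd, normalized = isNormalized(spectra))
}
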