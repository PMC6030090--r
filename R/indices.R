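#' Reflectance at a single nominal band
#'
#' Returns the reflectance at the grid wavelength nearest to `wl`; ties are
#' broken toward the lower wavelength.
#'
#' @param wavelength,reflectance one spectrum.
#' @param wl requested wavelength (nm); must lie within the grid coverage.
#' @return reflectance value.
#' @export
bandValue <- function(wavelength, reflectance, wl) {
    if (wl < wavelength[1] || wl > wavelength[length(wavelength)])
        stop("wavelength ", wl, " nm outside grid coverage [", wavelength[1],
             ", ", wavelength[length(wavelength)], "]", call. = FALSE)
    reflectance[which.min(abs(wavelength - wl))]   # first min = lower tie
}

#' Mean reflectance over a band range
#'
#' @param wavelength,reflectance one spectrum.
#' @param wlLo,wlHi inclusive range bounds (nm); at least one band required.
#' @return arithmetic mean of reflectance over the bands in range.
#' @export
bandMean <- function(wavelength, reflectance, wlLo, wlHi) {
    sel <- wavelength >= wlLo & wavelength <= wlHi
    if (!any(sel))
        stop("no bands in range [", wlLo, ", ", wlHi, "] nm", call. = FALSE)
    mean(reflectance[sel])
}

#' First-derivative spectrum
#'
#' Central finite difference `dR/dlambda` (per nm) on interior bands,
#' one-sided differences at the two ends; the wavelength grid is preserved.
#'
#' @param wavelength,reflectance one spectrum (>= 2 bands).
#' @return `data.frame` with `wavelength_nm` and `derivative`.
#' @export
firstDerivative <- function(wavelength, reflectance) {
    n <- length(wavelength)
    if (n < 2L) stop("need at least 2 bands", call. = FALSE)
    d <- numeric(n)
    d[1] <- (reflectance[2] - reflectance[1]) / (wavelength[2] - wavelength[1])
    d[n] <- (reflectance[n] - reflectance[n - 1]) /
        (wavelength[n] - wavelength[n - 1])
    if (n > 2L) {
        i <- 2:(n - 1)
        d[i] <- (reflectance[i + 1] - reflectance[i - 1]) /
            (wavelength[i + 1] - wavelength[i - 1])
    }
    data.frame(wavelength_nm = wavelength, derivative = d)
}

#' Red-edge position by linear extrapolation
#'
#' Estimates the red-edge position as the intersection of two straight lines
#' through points of the first-derivative spectrum: a far-red line through
#' (680, D680) and (700, D700), and an NIR line through (725, D725) and
#' (760, D760). An intersection outside 680–780 nm is returned with a warning
#' (attribute `flagged = TRUE`); parallel lines are a degeneracy error.
#'
#' @param wavelength,reflectance one spectrum covering 680–760 nm.
#' @return red-edge position (nm).
#' @export
repLinearExtrapolation <- function(wavelength, reflectance) {
    d <- firstDerivative(wavelength, reflectance)
    dv <- function(w) bandValue(d$wavelength_nm, d$derivative, w)
    m1 <- (dv(700) - dv(680)) / 20          # far-red flank
    b1 <- dv(680) - m1 * 680
    m2 <- (dv(760) - dv(725)) / 35          # NIR flank
    b2 <- dv(725) - m2 * 725
    if (abs(m1 - m2) < 1e-12 * max(abs(m1), abs(m2), 1e-12))
        stop("degenerate red-edge: derivative flanks are parallel",
             call. = FALSE)
    rep <- (b2 - b1) / (m1 - m2)
    if (rep < 680 || rep > 780) {
        warning("red-edge position ", format(rep, digits = 6),
                " nm outside 680-780 nm; flagged", call. = FALSE)
        attr(rep, "flagged") <- TRUE
    }
    rep
}

## ---- index registry -------------------------------------------------------
## Each entry: evaluation function over (wl, r), the printed formula, and
## whether the index is invariant to multiplicative scaling of the spectrum.

.deriv <- function(wl, r) firstDerivative(wl, r)$derivative

.indexRegistry <- list(
    VOG2 = list(
        formula = "(R734 - R747)/(R715 + R726)", invariant = TRUE,
        fn = function(wl, r) {
            R <- function(w) bandValue(wl, r, w)
            (R(734) - R(747)) / (R(715) + R(726))
        }),
    GIT = list(
        formula = "mean(R750-800)/mean(R695-740) - 1", invariant = TRUE,
        fn = function(wl, r)
            bandMean(wl, r, 750, 800) / bandMean(wl, r, 695, 740) - 1),
    RVI2 = list(
        formula = "R810/R560", invariant = TRUE,
        fn = function(wl, r) bandValue(wl, r, 810) / bandValue(wl, r, 560)),
    REPle = list(
        formula = "red-edge position, linear extrapolation of 1st derivative",
        invariant = TRUE,
        fn = function(wl, r) as.numeric(repLinearExtrapolation(wl, r))),
    VIopt = list(
        formula = "(1 + 0.45)(R800^2 + 1)/(R670 + 0.45)", invariant = FALSE,
        fn = function(wl, r) {
            R <- function(w) bandValue(wl, r, w)
            1.45 * (R(800)^2 + 1) / (R(670) + 0.45)
        }),
    DCNI = list(
        formula = "(R720 - R700)/(R700 - R670)/(R720 - R670 + 0.03)",
        invariant = FALSE,
        fn = function(wl, r) {
            R <- function(w) bandValue(wl, r, w)
            (R(720) - R(700)) / (R(700) - R(670)) / (R(720) - R(670) + 0.03)
        }),
    RIldB = list(
        formula = "R735/R720", invariant = TRUE,
        fn = function(wl, r) bandValue(wl, r, 735) / bandValue(wl, r, 720)),
    SDrSDb = list(
        formula = "sum 1st derivative 680-780 / sum 1st derivative 490-530",
        invariant = TRUE,
        fn = function(wl, r) {
            d <- .deriv(wl, r)
            sum(d[wl >= 680 & wl <= 780]) / sum(d[wl >= 490 & wl <= 530])
        }),
    Dr = list(
        formula = "max 1st derivative within 680-780", invariant = FALSE,
        fn = function(wl, r) {
            d <- .deriv(wl, r)
            max(d[wl >= 680 & wl <= 780])
        }),
    MCARI.MTVI2 = list(
        formula = "MCARI / MTVI2", invariant = FALSE,
        fn = function(wl, r) {
            R <- function(w) bandValue(wl, r, w)
            mcari <- ((R(700) - R(670)) - 0.2 * (R(700) - R(550))) *
                (R(700) / R(670))
            arg <- (2 * R(800) + 1)^2 - (6 * R(800) - 5 * sqrt(R(670))) - 0.5
            if (arg < 0) return(NaN)       # flagged missing, never complex
            mtvi2 <- 1.5 * (1.2 * (R(800) - R(550)) -
                            2.5 * (R(670) - R(550))) / sqrt(arg)
            mcari / mtvi2
        }),
    MSR705 = list(
        formula = "(R750/R705 - 1)/sqrt(R750/R705 + 1)", invariant = TRUE,
        fn = function(wl, r) {
            q <- bandValue(wl, r, 750) / bandValue(wl, r, 705)
            (q - 1) / sqrt(q + 1)
        }),
    TCARI.OSAVI = list(
        formula = "TCARI / OSAVI", invariant = FALSE,
        fn = function(wl, r) {
            R <- function(w) bandValue(wl, r, w)
            tcari <- 3 * ((R(700) - R(670)) -
                          0.2 * (R(700) - R(550)) * (R(700) / R(670)))
            osavi <- 1.16 * (R(800) - R(670)) / (R(800) + R(670) + 0.16)
            tcari / osavi
        }),
    mND705 = list(
        formula = "(R750 - R705)/(R750 + R705 - 2 R445)", invariant = TRUE,
        fn = function(wl, r) {
            R <- function(w) bandValue(wl, r, w)
            (R(750) - R(705)) / (R(750) + R(705) - 2 * R(445))
        }),
    MCARI = list(
        formula = "[(R700 - R670) - 0.2 (R700 - R550)] (R700/R670)",
        invariant = FALSE,
        fn = function(wl, r) {
            R <- function(w) bandValue(wl, r, w)
            ((R(700) - R(670)) - 0.2 * (R(700) - R(550))) * (R(700) / R(670))
        }),
    NPCI = list(
        formula = "(R680 - R430)/(R680 + R430)", invariant = TRUE,
        fn = function(wl, r) {
            R <- function(w) bandValue(wl, r, w)
            (R(680) - R(430)) / (R(680) + R(430))
        }),
    LCI = list(
        formula = "(R850 - R710)/(R850 + R680)", invariant = TRUE,
        fn = function(wl, r) {
            R <- function(w) bandValue(wl, r, w)
            (R(850) - R(710)) / (R(850) + R(680))
        }),
    RM = list(
        formula = "R750/R720 - 1", invariant = TRUE,
        fn = function(wl, r) bandValue(wl, r, 750) / bandValue(wl, r, 720) - 1),
    NDVIgb = list(
        formula = "(R573 - R440)/(R573 + R440)", invariant = TRUE,
        fn = function(wl, r) {
            R <- function(w) bandValue(wl, r, w)
            (R(573) - R(440)) / (R(573) + R(440))
        }),
    NDVI = list(
        formula = "(R800 - R670)/(R800 + R670)", invariant = TRUE,
        fn = function(wl, r) {
            R <- function(w) bandValue(wl, r, w)
            (R(800) - R(670)) / (R(800) + R(670))
        }),
    MTCI = list(
        formula = "(R750 - R710)/(R710 - R680)", invariant = TRUE,
        fn = function(wl, r) {
            R <- function(w) bandValue(wl, r, w)
            (R(750) - R(710)) / (R(710) - R(680))
        }),
    NDRE = list(
        formula = "(R790 - R720)/(R790 + R720)", invariant = TRUE,
        fn = function(wl, r) {
            R <- function(w) bandValue(wl, r, w)
            (R(790) - R(720)) / (R(790) + R(720))
        }),
    WRNI = list(
        formula = "(R735 - R720) R900 / [min(R930-980) (R735 + R720)]",
        invariant = TRUE,
        fn = function(wl, r) {
            R <- function(w) bandValue(wl, r, w)
            sel <- wl >= 930 & wl <= 980
            (R(735) - R(720)) * R(900) / (min(r[sel]) * (R(735) + R(720)))
        }))

.indexAliases <- c(RedEdgeNDVI = "NDRE", "Red-edgeNDVI" = "NDRE",
                   "MCARI/MTVI2" = "MCARI.MTVI2", "TCARI/OSAVI" = "TCARI.OSAVI",
                   "SDr/SDb" = "SDrSDb", "REP-le" = "REPle", "R-M" = "RM",
                   "NDVIg-b" = "NDVIgb", "RI_ldB" = "RIldB")

.resolveIndexName <- function(name) {
    if (name %in% names(.indexRegistry)) return(name)
    if (name %in% names(.indexAliases)) return(unname(.indexAliases[name]))
    stop("unknown spectral index '", name, "'; see indexRegistry()",
         call. = FALSE)
}

#' List the spectral index registry
#'
#' The 22 comparison indices: red-edge chlorophyll and nitrogen indices plus
#' derivative-based red-edge quantities. `scale_invariant` records whether the
#' index is unchanged under multiplicative scaling of the whole spectrum
#' (pure ratio forms are; indices with additive constants, and the
#' degree-one quantities MCARI and Dr, are not).
#'
#' @return `data.frame` with columns `name`, `formula`, `scale_invariant`.
#' @export
indexRegistry <- function() {
    data.frame(
        name = names(.indexRegistry),
        formula = vapply(.indexRegistry, `[[`, character(1), "formula"),
        scale_invariant = vapply(.indexRegistry, `[[`, logical(1),
                                 "invariant"),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Compute one spectral index for one spectrum
#'
#' @param wavelength,reflectance one spectrum covering the index's bands.
#' @param name index name from [indexRegistry()] (aliases such as
#'   `"RedEdgeNDVI"` for `NDRE` are accepted).
#' @param sampleId label used in error messages.
#' @return the index value.
#' @examples
#' wl <- 400:1050
#' r <- rep(0.1, length(wl)); r[wl >= 750] <- 0.5
#' computeIndex(wl, r, "NDVI")
#' @export
computeIndex <- function(wavelength, reflectance, name,
                         sampleId = "spectrum") {
    key <- .resolveIndexName(name)
    val <- .indexRegistry[[key]]$fn(wavelength, reflectance)
    if (!is.finite(val))
        stop("degenerate value for index '", key, "' on sample '", sampleId,
             "'", call. = FALSE)
    val
}

#' Compute all 22 spectral indices for a dataset
#'
#' One row per sample, indices in registry order. Per-sample degenerate values
#' (zero denominators, negative square-root arguments) are recorded as `NA`
#' with a warning rather than aborting the table.
#'
#' @param x a [SpectralSet-class] of preprocessed spectra.
#' @return `data.frame` with `sample_id`, `CN` and 22 index columns.
#' @export
computeAllIndices <- function(x) {
    stopifnot(methods::is(x, "SpectralSet"))
    wl <- wavelengths(x)
    mat <- reflectance(x)
    nms <- names(.indexRegistry)
    vals <- matrix(NA_real_, ncol(mat), length(nms),
                   dimnames = list(colnames(mat), nms))
    degenerate <- character()
    for (id in colnames(mat)) {
        for (nm in nms) {
            v <- tryCatch(
                suppressWarnings(.indexRegistry[[nm]]$fn(wl, mat[, id])),
                error = function(e) NA_real_)
            if (!is.finite(v)) {
                degenerate <- c(degenerate, paste0(nm, "[", id, "]"))
                v <- NA_real_
            }
            vals[id, nm] <- v
        }
    }
    if (length(degenerate))
        warning("degenerate index values recorded as missing: ",
                paste(degenerate, collapse = ", "), call. = FALSE)
    chem <- chemistry(x)
    cn <- if ("CN" %in% colnames(chem)) chem$CN else rep(NA_real_, nrow(chem))
    cbind(data.frame(sample_id = colnames(mat), CN = cn,
                     stringsAsFactors = FALSE),
          as.data.frame(vals))
}
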