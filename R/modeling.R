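#' Fit one univariate model family
#'
#' Fits one of the three candidate families relating a spectral feature and
#' leaf C/N: `linear` (`y = a + b x`, OLS), `exponential` (`y = a exp(b x)`,
#' OLS on `ln y`; requires all `y > 0`) or `logarithmic` (`y = a + b ln x`,
#' OLS on `ln x`; requires all `x > 0`). R² and RMSE are always computed on
#' the original `y` scale so the families are directly comparable; RMSE uses
#' denominator `n`. The p-value is the two-tailed slope significance of the
#' (possibly linearized) regression.
#'
#' When a family's precondition fails a classed condition
#' (`slopeCN_family_inapplicable`) is signalled so that [bestFit()] can skip
#' the family rather than abort.
#'
#' @param x predictor values.
#' @param y response values.
#' @param family `"linear"`, `"exponential"` or `"logarithmic"`.
#' @param direction label stored in the fit (`"feature->CN"` for estimation
#'   models, `"CN->feature"` for sensitivity fits).
#' @return a [ModelFit-class].
#' @examples
#' x <- 1:20
#' fitFamily(x, 2 + 0.5 * x, "linear")
#' @export
fitFamily <- function(x, y, family = c("linear", "exponential",
                                       "logarithmic"),
                      direction = "feature->CN") {
    family <- match.arg(family)
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L)
        .familyInapplicable(family, "need at least 3 complete observations")
    if (family == "exponential" && any(y <= 0))
        .familyInapplicable(family, "exponential fit requires all y > 0")
    if (family == "logarithmic" && any(x <= 0))
        .familyInapplicable(family, "logarithmic fit requires all x > 0")
    xx <- if (family == "logarithmic") log(x) else x
    yy <- if (family == "exponential") log(y) else y
    if (sd(xx) == 0)
        .familyInapplicable(family, "predictor has zero variance")
    fit <- lm(yy ~ xx)
    cf <- coef(fit)
    a <- if (family == "exponential") exp(unname(cf[1])) else unname(cf[1])
    b <- unname(cf[2])
    ## exact fits trigger a "perfect fit" warning in summary(); expected here
    pv <- suppressWarnings(summary(fit)$coefficients[2, 4])
    pred <- switch(family,
        linear      = a + b * x,
        exponential = a * exp(b * x),
        logarithmic = a + b * log(x))
    sse <- sum((y - pred)^2)
    sst <- sum((y - mean(y))^2)
    methods::new("ModelFit", family = family, a = a, b = b,
                 r2 = if (sst > 0) 1 - sse / sst else NA_real_,
                 rmse = sqrt(sse / n), pValue = pv,
                 significant = is.finite(pv) && pv < 0.01,
                 n = as.integer(n), direction = direction)
}

.familyInapplicable <- function(family, msg) {
    cond <- structure(
        class = c("slopeCN_family_inapplicable", "error", "condition"),
        list(message = paste0(family, ": ", msg), call = NULL))
    stop(cond)
}

#' Select the best-fitting model family
#'
#' Fits every applicable family with [fitFamily()] and returns the fit with
#' the highest R²; ties (difference below 1e-9) are broken by lower RMSE, then
#' by the fixed family order linear < logarithmic < exponential. A best fit
#' with `p >= 0.01` is returned flagged not-significant (the reporting
#' convention that prints a dash for such entries).
#'
#' @inheritParams fitFamily
#' @return a [ModelFit-class].
#' @export
bestFit <- function(x, y, direction = "feature->CN") {
    fams <- c("linear", "logarithmic", "exponential")   # tie-break order
    fits <- list()
    for (f in fams) {
        ft <- tryCatch(fitFamily(x, y, f, direction),
                       slopeCN_family_inapplicable = function(e) NULL)
        if (!is.null(ft)) fits[[f]] <- ft
    }
    if (length(fits) == 0L)
        stop("no model family is applicable to these data", call. = FALSE)
    score <- function(f) if (is.finite(f@r2)) f@r2 else -Inf
    best <- fits[[1]]
    for (ft in fits[-1]) {
        sf <- score(ft); sb <- score(best)
        tied <- (is.infinite(sf) && is.infinite(sb)) || abs(sf - sb) <= 1e-9
        if ((!tied && sf > sb) || (tied && ft@rmse < best@rmse))
            best <- ft
    }
    best
}

#' Per-band correlation between chemistry and normalized reflectance
#'
#' Pearson correlation of the chosen response against the normalized
#' reflectance at every band, with per-band two-tailed significance at
#' alpha = 0.01. Bands with zero variance yield `NA` and are flagged missing.
#'
#' @param x a normalized [SpectralSet-class] with chemistry attached
#'   (>= 3 samples).
#' @param response `"CN"`, `"LNC"` or `"LCC"`.
#' @return `data.frame` with `wavelength_nm`, `r`, `p`, `significant`.
#' @export
bandCorrelation <- function(x, response = c("CN", "LNC", "LCC")) {
    response <- match.arg(response)
    stopifnot(methods::is(x, "SpectralSet"))
    if (!isNormalized(x))
        stop("bandCorrelation() expects normalized spectra", call. = FALSE)
    chem <- chemistry(x)
    if (!response %in% colnames(chem) || all(is.na(chem[[response]])))
        stop("response '", response, "' not available in chemistry",
             call. = FALSE)
    resp <- chem[[response]]
    n <- length(resp)
    if (n < 3L) stop("need at least 3 samples", call. = FALSE)
    if (sd(resp) == 0)
        stop("response has zero variance", call. = FALSE)
    mat <- reflectance(x)
    bandSD <- apply(mat, 1, sd)
    r <- rep(NA_real_, nrow(mat))
    good <- bandSD > 0
    r[good] <- as.vector(cor(t(mat[good, , drop = FALSE]), resp))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    data.frame(wavelength_nm = wavelengths(x), r = r, p = p,
               significant = is.finite(p) & p < 0.01)
}

#' Divide values by their mean
#'
#' Used to put C/N, LNC and LCC on a common dimensionless scale for visual
#' comparison of their variation patterns.
#'
#' @param values numeric vector with non-zero mean.
#' @return `values / mean(values)` (mean exactly 1).
#' @export
normalizeByMean <- function(values) {
    m <- mean(values)
    if (!is.finite(m) || m == 0)
        stop("values must have a finite non-zero mean", call. = FALSE)
    values / m
}

#' Best-fit regression report for a feature table
#'
#' Runs [bestFit()] of C/N on every feature column of a table produced by
#' [buildFeatureTable()] or [computeAllIndices()].
#'
#' @param table `data.frame` with a `CN` column and feature columns.
#' @param features which columns to fit (default: all except `sample_id`,
#'   `CN`).
#' @return `data.frame` with `variable`, `family`, `a`, `b`, `R2`, `RMSE`,
#'   `p`, `significant`. Features where no family applies get NA rows.
#' @export
regressionReport <- function(table, features = NULL) {
    if (is.null(features))
        features <- setdiff(colnames(table), c("sample_id", "CN"))
    rows <- lapply(features, function(f) {
        ft <- tryCatch(bestFit(table[[f]], table$CN), error = function(e) NULL)
        if (is.null(ft))
            return(data.frame(variable = f, family = NA_character_,
                              a = NA_real_, b = NA_real_, R2 = NA_real_,
                              RMSE = NA_real_, p = NA_real_,
                              significant = FALSE, stringsAsFactors = FALSE))
        data.frame(variable = f, family = ft@family, a = ft@a, b = ft@b,
                   R2 = ft@r2, RMSE = ft@rmse, p = ft@pValue,
                   significant = ft@significant, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
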