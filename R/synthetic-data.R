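#' Synthetic-dataset generator configuration
#'
#' Parameters of the parametric canopy-spectrum generator used to exercise the
#' whole pipeline without field data. The defaults describe a study-scale
#' campaign: C/N uniform over 7.5-16.6 (the observed range of cereal canopies
#' the method targets), leaf carbon concentration nearly constant (mean 45
#' g/100 g, 3 % CV) so that C/N variation is carried almost entirely by leaf
#' nitrogen (`LNC = LCC / CN`), per-band Gaussian noise of 0.003 reflectance
#' units, and a multiplicative illumination factor drawn from 0.5-1.2 per
#' sample emulating variable sky conditions. In two-species mode the samples
#' split 120/38 wheat/barley (the combined-campaign proportions) and barley
#' spectra receive additive baseline and NIR-tilt offsets; those offsets move
#' single slope features between species but cancel in ratio and combined
#' features.
#'
#' @param nSamples number of samples.
#' @param cnRange C/N range, uniform draw.
#' @param lccMean,lccCV mean and coefficient of variation of LCC (g/100 g).
#' @param noiseSD additive per-band Gaussian noise, reflectance units.
#' @param illuminationRange multiplicative illumination factor interval.
#' @param twoSpecies split samples into wheat/barley with species offsets?
#' @param wheatFraction fraction of samples labelled wheat in two-species
#'   mode.
#' @param speciesShift additive offsets applied to barley spectra: `baseline`
#'   (reflectance units, all bands) and `nirTilt` (reflectance per nm on the
#'   NIR plateau slope).
#' @param shape named list of shape-parameter maps; each entry `c(a, b)` is
#'   evaluated as `a + b / CN` (1/CN is the chlorophyll proxy). See
#'   [spectrumFromCN()].
#' @param seed integer seed governing all draws.
#' @return a list of class `GeneratorConfig`.
#' @export
generatorConfig <- function(nSamples = 158,
                            cnRange = c(7.5, 16.6),
                            lccMean = 45.0, lccCV = 0.03,
                            noiseSD = 0.003,
                            illuminationRange = c(0.5, 1.2),
                            twoSpecies = TRUE,
                            wheatFraction = 120 / 158,
                            speciesShift = list(baseline = 0.04,
                                                nirTilt = 6e-5),
                            shape = NULL,
                            seed = 1L) {
    if (cnRange[1] >= cnRange[2]) stop("cnRange must be increasing",
                                       call. = FALSE)
    if (lccCV < 0 || noiseSD < 0) stop("dispersions must be >= 0",
                                       call. = FALSE)
    if (is.null(shape)) shape <- .defaultShape
    structure(list(nSamples = as.integer(nSamples), cnRange = cnRange,
                   lccMean = lccMean, lccCV = lccCV, noiseSD = noiseSD,
                   illuminationRange = illuminationRange,
                   twoSpecies = isTRUE(twoSpecies),
                   wheatFraction = wheatFraction,
                   speciesShift = speciesShift, shape = shape,
                   seed = as.integer(seed)),
              class = "GeneratorConfig")
}

## Shape-parameter maps, each evaluated as a + b * (1/CN). 1/CN proxies
## chlorophyll: low C/N = N-rich, chlorophyll-rich canopy. The maps encode the
## qualitative shape ordering of cereal canopy spectra across C/N levels:
## low C/N -> darker visible region, deeper red well, steeper red edge,
## flatter green flank and flatter NIR plateau; high C/N -> taller, broader
## visible peak and brighter NIR.
.defaultShape <- list(
    visBase       = c(0.075, -0.40),   # visible baseline reflectance
    greenAmp      = c(0.12, -0.60),    # green-peak amplitude (550 nm)
    greenWidth    = c(58, -120),       # green-peak Gaussian width (nm)
    redWellDepth  = c(0, 0.08),        # extra absorption at the red well
    redWellWidth  = 22,                # red-well Gaussian width (nm)
    redEdgePos    = c(725, -80),       # logistic inflection (nm)
    redEdgeScale  = c(14, -60),        # logistic scale (nm); smaller = steeper
    nirLevel      = c(0.52, -0.60),    # NIR plateau level at 835 nm
    nirTilt       = c(3.0e-4, -1.6e-3),# NIR plateau slope (refl / nm)
    waterDipDepth = 0.035,             # 960 nm water-absorption dip
    waterDipWidth = 22,
    waterDipCenter = 965)

.shapeValue <- function(shape, name, cn) {
    v <- shape[[name]]
    if (length(v) == 1L) v else v[1] + v[2] / cn
}

#' Generate a leaf-chemistry table
#'
#' Draws C/N uniformly over the configured range and LCC with a small
#' coefficient of variation, then sets `LNC = LCC / CN` so that `CN = LCC /
#' LNC` holds exactly. LCC thus varies gently while LNC varies strongly and
#' carries nearly all the C/N signal (C/N tracks 1/LNC almost perfectly).
#'
#' @param config a [generatorConfig()] list.
#' @return `data.frame` with `sample_id`, `species`, `LNC`, `LCC`, `CN`.
#' @export
chemistryTable <- function(config = generatorConfig()) {
    n <- config$nSamples
    set.seed(config$seed)
    cn <- runif(n, config$cnRange[1], config$cnRange[2])
    lcc <- rnorm(n, config$lccMean, config$lccMean * config$lccCV)
    lcc <- pmax(lcc, config$lccMean * 0.5)   # guard: LCC must stay positive
    species <- if (config$twoSpecies) {
        nWheat <- round(n * config$wheatFraction)
        c(rep("wheat", nWheat), rep("barley", n - nWheat))
    } else rep("wheat", n)
    data.frame(sample_id = sprintf("S%03d", seq_len(n)), species = species,
               LNC = lcc / cn, LCC = lcc, CN = cn, stringsAsFactors = FALSE)
}

#' Generate one canopy-like reflectance spectrum for a given C/N
#'
#' Builds a raw reflectance spectrum on the 400-1050 nm 1 nm grid as the sum
#' of a visible baseline, a Gaussian green peak at 550 nm, an inverted
#' Gaussian red well at 670 nm, a logistic red edge rising to a gently tilted
#' NIR plateau, and an inverted Gaussian water dip near 960 nm; every shape
#' parameter is an affine function of 1/CN (see [generatorConfig()]).
#' Additive band noise and the multiplicative illumination factor are applied
#' last, so mean normalization removes the illumination factor exactly.
#'
#' @param cn leaf C/N (> 0).
#' @param illumination multiplicative illumination factor.
#' @param species `"wheat"` or `"barley"`; barley receives the configured
#'   additive baseline/NIR-tilt offsets.
#' @param config a [generatorConfig()] list.
#' @param seed optional integer; if given, the band noise is drawn under this
#'   seed so the same `(cn, seed)` always yields the identical spectrum.
#' @return numeric reflectance vector on `400:1050` nm (names omitted).
#' @export
spectrumFromCN <- function(cn, illumination = 1, species = "wheat",
                           config = generatorConfig(), seed = NULL) {
    if (cn <= 0) stop("cn must be positive", call. = FALSE)
    wl <- 400:1050
    sh <- config$shape
    baseShift <- if (species == "barley") config$speciesShift$baseline else 0
    tiltShift <- if (species == "barley") config$speciesShift$nirTilt else 0

    vis <- .shapeValue(sh, "visBase", cn) +
        .shapeValue(sh, "greenAmp", cn) *
            exp(-(wl - 550)^2 / (2 * .shapeValue(sh, "greenWidth", cn)^2)) -
        .shapeValue(sh, "redWellDepth", cn) *
            exp(-(wl - 670)^2 / (2 * sh$redWellWidth^2))
    plat <- .shapeValue(sh, "nirLevel", cn) +
        (.shapeValue(sh, "nirTilt", cn) + tiltShift) * (wl - 835)
    edge <- stats::plogis((wl - .shapeValue(sh, "redEdgePos", cn)) /
                          .shapeValue(sh, "redEdgeScale", cn))
    r <- vis + (plat - vis) * edge -
        sh$waterDipDepth *
            exp(-(wl - sh$waterDipCenter)^2 / (2 * sh$waterDipWidth^2)) +
        baseShift
    if (any(r <= 0) || any(r >= 1))
        stop("shape parameters drive reflectance outside (0, 1) for cn = ",
             cn, call. = FALSE)
    if (config$noiseSD > 0) {
        if (!is.null(seed)) set.seed(seed)
        r <- r + rnorm(length(wl), 0, config$noiseSD)
        r <- pmax(r, 1e-6)     # non-negativity guard; rare by construction
    }
    r * illumination
}

#' Generate a full synthetic dataset
#'
#' Chemistry table plus one raw spectrum per sample (illumination factor and
#' band noise drawn per sample), assembled into a [SpectralSet-class]. The
#' whole dataset is a deterministic function of the configuration, including
#' its seed.
#'
#' @param config a [generatorConfig()] list.
#' @return a raw (unnormalized) `SpectralSet` with chemistry in `colData`.
#' @examples
#' ds <- generateDataset(generatorConfig(nSamples = 10, seed = 7))
#' ds
#' @export
generateDataset <- function(config = generatorConfig()) {
    chem <- chemistryTable(config)
    n <- nrow(chem)
    set.seed(config$seed + 10000L)
    illum <- runif(n, config$illuminationRange[1], config$illuminationRange[2])
    wl <- 400:1050
    mat <- matrix(NA_real_, length(wl), n,
                  dimnames = list(NULL, chem$sample_id))
    for (i in seq_len(n))
        mat[, i] <- spectrumFromCN(chem$CN[i], illum[i], chem$species[i],
                                   config, seed = config$seed + 20000L + i)
    SpectralSet(mat, wl,
                sampleData = chem[, c("species", "LNC", "LCC", "CN")],
                normalized = FALSE)
}
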