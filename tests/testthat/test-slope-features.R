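plantedSlopes <- c(0.002, 0.004, -0.003, 0.010, 0.0002, -0.001, 0.0005)

test_that("segment slope fitting is exact on lines and matches the OLS
           closed form on noisy segments", {
    wl <- c(400, 425, 450, 475, 500)
    f <- fitSegmentSlope(wl, 0.001 * wl + 0.05, 400, 500)
    expect_equal(f$slope, 0.001, tolerance = 1e-12)
    expect_equal(f$intercept, 0.05, tolerance = 1e-12)
    expect_identical(f$nBands, 5L)

    expect_equal(fitSegmentSlope(wl, rep(1, 5), 400, 500)$slope, 0)
    expect_error(fitSegmentSlope(wl, rep(1, 5), 600, 700), "fewer than 2")

    # independent closed-form OLS oracle on noisy segments
    set.seed(42)
    for (i in 1:100) {
        x <- seq(680, 760, by = 1)
        y <- 0.01 * x + rnorm(length(x), sd = 0.05)
        got <- fitSegmentSlope(x, y, 680, 760)$slope
        oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
        expect_lt(abs(got - oracle), 1e-10)
    }
})

test_that("single slopes of a piecewise-linear spectrum are recovered exactly", {
    s <- pwlSpectrum(plantedSlopes)
    got <- extractSingleSlopes(s$wl, s$r)
    expect_identical(names(got),
                     paste0("K_", c("pb", "ge", "gprv", "re", "nir", "nir2",
                                    "nir3")))
    expect_equal(unname(got), plantedSlopes, tolerance = 1e-12)

    expect_error(extractSingleSlopes(400:900, rep(1, 501)),
                 "does not cover")
})

test_that("ratio and combined features follow their defining arithmetic", {
    s <- pwlSpectrum(plantedSlopes)
    fs <- extractFeatureSet(s$wl, s$r)
    expect_length(fs, 22)
    expect_identical(names(fs), slopeFeatureNames())

    kre <- plantedSlopes[4]
    expect_equal(unname(fs["K_pb_over_K_re"]), plantedSlopes[1] / kre,
                 tolerance = 1e-12)
    expect_equal(unname(fs["K_ge_plus_K_nir_over_2K_re"]),
                 (plantedSlopes[2] + plantedSlopes[5]) / (2 * kre),
                 tolerance = 1e-12)
    expect_equal(unname(fs["K_pb_plus_K_ge_over_2K_re"]),
                 (plantedSlopes[1] + plantedSlopes[2]) / (2 * kre),
                 tolerance = 1e-12)

    flat <- rep(1, 651)
    expect_error(extractFeatureSet(400:1050, flat, sampleId = "flat1"),
                 "degenerate red-edge.*flat1")
})

test_that("custom combined pairs are honoured", {
    s <- pwlSpectrum(plantedSlopes)
    fs <- extractFeatureSet(s$wl, s$r,
                            combinedPairs = list(c("nir", "nir3")))
    expect_true("K_nir_plus_K_nir3_over_2K_re" %in% names(fs))
    expect_equal(unname(fs["K_nir_plus_K_nir3_over_2K_re"]),
                 (plantedSlopes[5] + plantedSlopes[7]) /
                     (2 * plantedSlopes[4]), tolerance = 1e-12)
})

test_that("feature tables have deterministic shape and order", {
    cfg <- generatorConfig(nSamples = 10, seed = 9)
    pp <- preprocessSpectra(generateDataset(cfg))
    tab <- buildFeatureTable(pp)
    expect_identical(dim(tab), c(10L, 24L))
    expect_identical(colnames(tab), c("sample_id", "CN", slopeFeatureNames()))
    expect_false(anyNA(tab))

    shuffled <- pp[, c(4, 1, 9, 2, 3, 10, 6, 5, 8, 7)]
    tab2 <- buildFeatureTable(methods::as(shuffled, "SpectralSet"))
    rownames(tab2) <- tab2$sample_id
    expect_equal(tab2[tab$sample_id, ], tab, ignore_attr = TRUE)

    expect_error(buildFeatureTable(generateDataset(cfg)), "normalized")
})

test_that("feature-table extraction aborts naming a degenerate sample", {
    wl <- 400:1050
    good <- canopySpectrum(12)
    mat <- cbind(ok = good, flatX = rep(1, length(wl)))
    x <- SpectralSet(mat, wl, sampleData = data.frame(CN = c(10, 11)),
                     normalized = TRUE)
    expect_error(buildFeatureTable(x), "flatX")
})

test_that("slope features inherit the preprocessing illumination invariance,
           and only ratio/combined features are invariant to rescaling the
           normalized spectrum itself", {
    cfg <- generatorConfig(nSamples = 1, noiseSD = 0, twoSpecies = FALSE,
                           seed = 2)
    r <- spectrumFromCN(10, 1, "wheat", cfg)
    wl <- 400:1050
    f <- function(refl) {
        x <- SpectralSet(matrix(refl, dimnames = list(NULL, "a")), wl)
        s <- preprocessSpectra(x)
        extractFeatureSet(wavelengths(s), reflectance(s)[, 1])
    }
    expect_equal(f(r), f(0.6 * r), tolerance = 1e-9)

    # rescaling the *normalized* curve: degree-0 features unchanged,
    # single slopes scale linearly
    s <- pwlSpectrum(plantedSlopes)
    a <- extractFeatureSet(s$wl, s$r)
    b <- extractFeatureSet(s$wl, 2 * s$r)
    ratioCols <- grep("over", names(a))
    expect_equal(a[ratioCols], b[ratioCols], tolerance = 1e-12)
    expect_equal(2 * a[-ratioCols], b[-ratioCols], tolerance = 1e-12)
})
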