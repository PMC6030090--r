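test_that("band accessor picks the nearest band, ties toward lower", {
    wl1 <- 400:1050
    r1 <- (wl1 - 400) / 1000
    expect_equal(bandValue(wl1, r1, 670), r1[wl1 == 670])

    wl2 <- seq(401, 1049, by = 2)          # ... 669, 671 ...
    r2 <- seq_along(wl2)
    expect_equal(bandValue(wl2, r2, 670), r2[wl2 == 669])

    expect_error(bandValue(wl1, r1, 2500), "outside grid coverage")
})

test_that("band means average the inclusive range", {
    wl <- 400:1050
    expect_equal(bandMean(wl, rep(0.4, length(wl)), 750, 800), 0.4)
    ramp <- 0.1 + (wl - 750) * (0.2 / 50)      # 0.1 at 750, 0.3 at 800
    expect_equal(bandMean(wl, ramp, 750, 800), 0.2)
    expect_error(bandMean(wl, ramp, 1100, 1200), "no bands")

    # GIT from two flat plateaus
    r <- stepSpectrum(c(400, 745), c(0.25, 0.5), wl)
    expect_equal(computeIndex(wl, r, "GIT"), 1.0)
})

test_that("first derivative is exact for affine spectra and locates the
           logistic inflection", {
    wl <- 400:1050
    d <- firstDerivative(wl, 0.001 * wl)
    expect_equal(d$derivative, rep(0.001, length(wl)), tolerance = 1e-12)
    expect_equal(firstDerivative(wl, rep(0.3, length(wl)))$derivative,
                 rep(0, length(wl)))

    r <- 0.05 + 0.4 * plogis((wl - 722) / 9)
    dr <- firstDerivative(wl, r)
    sel <- wl >= 680 & wl <= 780
    peak <- wl[sel][which.max(dr$derivative[sel])]
    expect_lt(abs(peak - 722), 2)
    expect_error(firstDerivative(700, 0.1), "at least 2 bands")
})

test_that("red-edge position by linear extrapolation solves the constructed
           two-line crossing exactly", {
    wl <- 400:1050
    # derivative: zero, then a rising far-red flank (slope 4e-4 from 650 nm),
    # then a falling NIR flank through the same point at 718 nm
    d <- ifelse(wl < 650, 0,
         ifelse(wl <= 712, 4e-4 * (wl - 660),
         ifelse(wl <= 830, 0.0232 - 2e-4 * (wl - 718), 0.0008)))
    r <- spectrumFromDerivative(wl, d)
    expect_equal(repLinearExtrapolation(wl, r), 718, tolerance = 1e-9)

    # symmetric Gaussian derivative peak centred at 720
    dg <- 0.01 * exp(-(wl - 720)^2 / (2 * 20^2))
    rg <- spectrumFromDerivative(wl, dg)
    expect_lt(abs(repLinearExtrapolation(wl, rg) - 720), 2)

    expect_error(repLinearExtrapolation(wl, rep(0.3, length(wl))),
                 "parallel")
})

test_that("index formulas reproduce their analytic micro-examples", {
    wl <- 400:1050
    ndvi <- stepSpectrum(c(400, 700), c(0.1, 0.5), wl)   # R670=.1 R800=.5
    expect_equal(computeIndex(wl, ndvi, "NDVI"), 0.4 / 0.6,
                 tolerance = 1e-12)

    mtci <- stepSpectrum(c(400, 695, 730), c(0.2, 0.3, 0.5), wl)
    expect_equal(computeIndex(wl, mtci, "MTCI"), 2.0, tolerance = 1e-12)

    flatTop <- stepSpectrum(c(400, 690), c(0.2, 0.5), wl)  # R750 == R705
    expect_equal(computeIndex(wl, flatTop, "MSR705"), 0, tolerance = 1e-12)

    expect_equal(computeIndex(wl, ndvi, "RVI2"), 0.5 / 0.1)
    expect_equal(computeIndex(wl, flatTop, "RIldB"), 1.0)  # R735 == R720
    expect_equal(computeIndex(wl, ndvi, "VIopt"),
                 1.45 * (0.25 + 1) / (0.1 + 0.45), tolerance = 1e-12)
    # DCNI on three steps: R670=.2, R700=.3, R720=.5
    dcni <- stepSpectrum(c(400, 685, 710), c(0.2, 0.3, 0.5), wl)
    expect_equal(computeIndex(wl, dcni, "DCNI"),
                 (0.5 - 0.3) / (0.3 - 0.2) / (0.5 - 0.2 + 0.03),
                 tolerance = 1e-12)
    # WRNI: levels R720=.3, R735=.45, R900=.5, min over 930-980 = .4
    wrni <- stepSpectrum(c(400, 728, 800, 925, 985),
                         c(0.3, 0.45, 0.5, 0.4, 0.5), wl)
    expect_equal(computeIndex(wl, wrni, "WRNI"),
                 (0.45 - 0.3) * 0.5 / (0.4 * (0.45 + 0.3)),
                 tolerance = 1e-12)

    expect_error(computeIndex(wl, ndvi, "NOPE"), "unknown spectral index")
    # the Red-edgeNDVI alias resolves to NDRE
    expect_equal(computeIndex(wl, ndvi, "RedEdgeNDVI"),
                 computeIndex(wl, ndvi, "NDRE"))
})

test_that("scale-invariance classification of all 22 indices holds", {
    wl <- 400:1050
    r <- canopySpectrum(11)
    reg <- indexRegistry()
    expect_identical(nrow(reg), 22L)
    for (i in seq_len(nrow(reg))) {
        v1 <- computeIndex(wl, r, reg$name[i])
        v2 <- computeIndex(wl, 3 * r, reg$name[i])
        if (reg$scale_invariant[i]) {
            expect_equal(v2, v1, tolerance = 1e-9, label = reg$name[i])
        } else {
            expect_gt(abs(v2 - v1), 1e-6 * max(abs(v1), 1))
        }
    }
})

test_that("normalized-difference indices stay within [-1, 1]", {
    set.seed(8)
    wl <- 400:1050
    for (i in 1:5) {
        r <- runif(length(wl), 0.01, 0.9)
        for (nm in c("NDVI", "NDRE", "NPCI", "NDVIgb")) {
            v <- computeIndex(wl, r, nm)
            expect_gte(v, -1)
            expect_lte(v, 1)
        }
    }
})

test_that("the dataset-level index table is deterministic and records
           degenerate values as missing", {
    cfg <- generatorConfig(nSamples = 10, seed = 4)
    pp <- preprocessSpectra(generateDataset(cfg))
    t1 <- computeAllIndices(pp)
    t2 <- computeAllIndices(pp)
    expect_identical(dim(t1), c(10L, 24L))
    expect_identical(colnames(t1), c("sample_id", "CN", indexRegistry()$name))
    expect_identical(t1, t2)
    expect_false(anyNA(t1[, indexRegistry()$name]))

    wl <- 400:1050
    flat <- SpectralSet(matrix(0.3, length(wl), 1,
                               dimnames = list(NULL, "flat")), wl)
    expect_warning(tf <- computeAllIndices(flat), "degenerate")
    expect_equal(tf$NDVI, 0)          # 0 / positive denominator
    expect_true(is.na(tf$MTCI))       # R710 == R680
})
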