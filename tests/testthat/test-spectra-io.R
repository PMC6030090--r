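test_that("wide and long CSV round trips preserve spectra to 1e-12", {
    set.seed(11)
    wl <- 400:1050
    mat <- sapply(1:3, function(i) runif(length(wl), 0.05, 0.6))
    colnames(mat) <- c("A", "B", "C")
    x <- SpectralSet(mat, wl)
    for (layout in c("wide", "long")) {
        f <- withr::local_tempfile(fileext = ".csv")
        writeSpectra(x, f, layout)
        y <- readSpectra(f, layout)
        expect_identical(dim(y), c(651L, 3L))
        expect_equal(wavelengths(y), wl)
        expect_lt(max(abs(reflectance(y) - mat)), 1e-12)
    }
})

test_that("long layout rows may arrive shuffled", {
    wl <- seq(400, 1050, by = 10)
    r <- seq_along(wl) / 100
    f <- withr::local_tempfile(fileext = ".csv")
    df <- data.frame(sample_id = "s1", wavelength_nm = wl, reflectance = r)
    set.seed(2)
    write.csv(df[sample(nrow(df)), ], f, row.names = FALSE)
    y <- readSpectra(f, "long")
    expect_equal(wavelengths(y), wl)
    expect_equal(unname(reflectance(y)[, 1]), r)
})

test_that("malformed spectral files produce descriptive parse errors", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("wavelength_nm,s1", "400,0.1", "700,0.2", "700,0.3"), f)
    expect_error(readSpectra(f, "wide"), "duplicated wavelength 700")
    writeLines(c("wavelength_nm,s1", "400,0.1", "500,oops"), f)
    expect_error(readSpectra(f, "wide"), "non-numeric.*s1")
    writeLines("wavelength_nm,s1", f)
    expect_error(readSpectra(f, "wide"), "empty")
    writeLines(c("sample_id,wavelength_nm,reflectance",
                 "a,400,0.1", "a,500,0.2", "b,400,0.1", "b,600,0.2"), f)
    expect_error(readSpectra(f, "long"), "grid mismatch")
})

test_that("sample records fill and validate C/N = LCC/LNC", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,species,LNC,LCC,CN",
                 "a,wheat,3.0,45.0,", "b,barley,,,10.0"), f)
    s <- readSamples(f)
    expect_equal(s$CN, c(15.0, 10.0))
    expect_true(is.na(s$LNC[2]) && is.na(s$LCC[2]))

    writeLines(c("sample_id,species,LNC,LCC,CN", "a,wheat,3.0,45.0,12.0"), f)
    expect_error(readSamples(f), "inconsistent")
    writeLines(c("sample_id,species,LNC,LCC,CN", "a,wheat,,45.0,"), f)
    expect_error(readSamples(f), "need CN or both")
    writeLines(c("sample_id,species,LNC,LCC,CN", "a,wheat,0,45.0,"), f)
    expect_error(readSamples(f), "positive")
})

test_that("join keeps the intersection and reports dropped ids", {
    wl <- seq(400, 1050, by = 5)
    mat <- matrix(runif(length(wl) * 3, 0.1, 0.5), ncol = 3,
                  dimnames = list(NULL, c("a", "b", "c")))
    x <- SpectralSet(mat, wl)
    samp <- data.frame(sample_id = c("a", "b", "z"), species = "wheat",
                       LNC = 3, LCC = 45, CN = 15)
    expect_warning(ds <- joinDataset(x, samp), "dropped.*c.*z")
    expect_identical(colnames(ds), c("a", "b"))
    expect_equal(chemistry(ds)$CN, c(15, 15))

    expect_error(joinDataset(x, data.frame(sample_id = "q", CN = 9)),
                 "no sample ids shared")
})

test_that("joining spectra on different grids is a grid-mismatch error", {
    x1 <- SpectralSet(matrix(runif(131, 0.1, 0.5),
                             dimnames = list(NULL, "a")),
                      seq(400, 1050, by = 5))
    x2 <- SpectralSet(matrix(runif(66, 0.1, 0.5), dimnames = list(NULL, "b")),
                      seq(400, 1050, by = 10))
    samp <- data.frame(sample_id = c("a", "b"), CN = c(9, 12))
    expect_error(joinDataset(list(x1, x2), samp), "grid mismatch")
})

test_that("join result is independent of sample-table row order", {
    set.seed(5)
    wl <- seq(400, 1050, by = 5)
    mat <- matrix(runif(length(wl) * 4, 0.1, 0.5), ncol = 4,
                  dimnames = list(NULL, paste0("s", 1:4)))
    x <- SpectralSet(mat, wl)
    samp <- data.frame(sample_id = paste0("s", 1:4), CN = c(9, 11, 13, 15))
    d1 <- joinDataset(x, samp)
    d2 <- joinDataset(x, samp[sample(4), ])
    expect_identical(chemistry(d1), chemistry(d2))
    expect_identical(reflectance(d1), reflectance(d2))
})

test_that("SpectralSet validity rejects bad grids and false normalization", {
    expect_error(SpectralSet(matrix(1:4, 2), c(500, 400)),
                 "strictly increasing")
    expect_error(SpectralSet(matrix(c(0.1, NA), 2), c(400, 500)), "finite")
    expect_error(SpectralSet(matrix(c(0.1, 0.4), 2), c(400, 500),
                             normalized = TRUE), "mean 1")
})
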