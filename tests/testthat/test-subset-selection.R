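# independent oracle: enumerate all subsets with plain lm.fit
oracleBest <- function(X, y, k) {
    combos <- combn(ncol(X), k)
    rs <- apply(combos, 2, function(idx)
        sum(lm.fit(cbind(1, X[, idx, drop = FALSE]), y)$residuals^2))
    list(rss = min(rs), idx = combos[, which.min(rs)])
}

test_that("the inner least-squares evaluator recovers exact coefficients and
           flags degeneracy", {
    set.seed(1)
    X <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- 1 + 2 * X[, 1] - X[, 2]
    f <- olsMulti(X[, 1:2], y)
    expect_equal(unname(f$coefficients), c(1, 2, -1), tolerance = 1e-10)
    expect_equal(f$rss, 0, tolerance = 1e-18)
    expect_equal(f$r2, 1, tolerance = 1e-12)

    Xd <- cbind(X[, 1, drop = FALSE], dup = X[, 1])
    yn <- y + rnorm(50, sd = 0.1)
    expect_warning(fd <- olsMulti(Xd, yn), "degenerate")
    f1 <- olsMulti(X[, 1, drop = FALSE], yn)
    expect_equal(fd$rss, f1$rss, tolerance = 1e-9)

    # y orthogonal to all centred columns => R2 = 0
    z <- rnorm(50)
    yo <- qr.resid(qr(cbind(1, X)), z) + 5
    fo <- olsMulti(X, yo)
    expect_equal(fo$r2, 0, tolerance = 1e-9)

    expect_error(olsMulti(matrix(rnorm(12), 3, 4), rnorm(3)),
                 "more observations")
})

test_that("branch and bound equals explicit enumeration at p = 3 and finds
           planted supports", {
    set.seed(2)
    X <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
    y <- 0.5 * X[, 1] + rnorm(40)
    bb <- branchAndBound(X, y, 2)
    fits <- combn(3, 2, function(idx)
        sum(lm.fit(cbind(1, X[, idx]), y)$residuals^2))
    expect_equal(bb@rss, min(fits), tolerance = 1e-9)

    set.seed(3)
    Xp <- matrix(rnorm(500), 50, 10,
                 dimnames = list(NULL, paste0("f", 1:10)))
    yp <- 2 * Xp[, 2] - 1.5 * Xp[, 5] + rnorm(50, sd = 0.01)
    expect_identical(members(branchAndBound(Xp, yp, 2)), c("f2", "f5"))

    full <- branchAndBound(Xp, yp, 10)
    expect_identical(members(full), paste0("f", 1:10))
    expect_equal(full@rss, sum(lm.fit(cbind(1, Xp), yp)$residuals^2),
                 tolerance = 1e-9)

    expect_error(branchAndBound(Xp, yp, 11), "k must be")
})

test_that("branch and bound matches the exhaustive oracle across random
           instances and all k", {
    set.seed(10)
    X <- matrix(rnorm(50 * 12), 50, 12)
    colnames(X) <- paste0("v", 1:12)
    y <- X[, 3] - 0.7 * X[, 8] + 0.4 * X[, 11] + rnorm(50, sd = 0.5)
    for (k in 1:6) {
        bb <- branchAndBound(X, y, k)
        ex <- exhaustiveSearch(X, y, k)
        or <- oracleBest(X, y, k)
        expect_equal(bb@rss, or$rss, tolerance = 1e-9)
        expect_equal(ex@rss, or$rss, tolerance = 1e-9)
        expect_identical(members(bb), members(ex))
    }
})

test_that("the subset path is monotone and prunes relative to enumeration", {
    set.seed(11)
    X <- matrix(rnorm(50 * 10), 50, 10)
    colnames(X) <- paste0("v", 1:10)
    y <- 1.5 * X[, 1] + X[, 4] + 0.5 * X[, 7] + rnorm(50, sd = 0.3)
    path <- subsetPath(X, y, 6)
    tab <- pathTable(path)
    expect_true(all(diff(tab$rss) <= 1e-9))
    expect_true(all(diff(tab$r2) >= -1e-9))
    expect_true(all(diff(tab$rmse) <= 1e-9))
    expect_lt(nodesExplored(path), exhaustiveNodes(path))

    # noiseless truth on 3 features: R2 = 1 from k = 3 onward
    y0 <- 2 + X[, 2] - X[, 5] + 0.5 * X[, 9]
    p0 <- subsetPath(X, y0, 5)
    r2s <- pathTable(p0)$r2
    expect_lt(r2s[2], 1 - 1e-6)
    expect_equal(r2s[3:5], rep(1, 3), tolerance = 1e-9)
    expect_identical(members(p0@results[[3]]), c("v2", "v5", "v9"))
})

test_that("stableK flags the elbow of the path", {
    set.seed(12)
    X <- matrix(rnorm(60 * 8), 60, 8)
    y <- X[, 1] + X[, 2] + rnorm(60, sd = 0.05)
    path <- subsetPath(X, y, 5)
    expect_identical(stableK(path), 3L)   # gains vanish after k = 2
})

test_that("stored subset models evaluate consistently and degrade across a
           shifted population", {
    cfg <- generatorConfig(nSamples = 60, twoSpecies = FALSE, seed = 14)
    tab <- buildFeatureTable(preprocessSpectra(generateDataset(cfg)))
    singles <- paste0("K_", c("pb", "ge", "gprv", "re", "nir", "nir2",
                              "nir3"))
    X <- as.matrix(tab[, singles])
    res <- branchAndBound(X, tab$CN, 3)
    ev <- applyModel(res, tab)
    expect_equal(ev$r2, r2(res), tolerance = 1e-9)
    expect_equal(ev$rmse, rmse(res), tolerance = 1e-9)

    perm <- tab[sample(nrow(tab)), ]
    evp <- applyModel(res, perm)
    expect_equal(evp$r2, ev$r2, tolerance = 1e-12)

    # wheat-trained model applied to a barley-shifted population
    cfgB <- generatorConfig(nSamples = 60, twoSpecies = TRUE,
                            wheatFraction = 0, seed = 15)
    tabB <- buildFeatureTable(preprocessSpectra(generateDataset(cfgB)))
    evB <- applyModel(res, tabB)
    expect_lt(evB$r2, r2(res))

    expect_error(applyModel(res, tab[, 1:4]), "lacks member")
})
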