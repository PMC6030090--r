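# Shared fixtures, all built in code.

# Piecewise-linear spectrum with planted segment slopes, vertically shifted so
# its mean is exactly 1 (a constant shift leaves every segment slope intact).
pwlSpectrum <- function(slopes,
                        bp = c(400, 500, 550, 680, 760, 910, 960, 1050),
                        step = 1) {
    stopifnot(length(slopes) == length(bp) - 1)
    wl <- seq(min(bp), max(bp), by = step)
    v <- c(0, cumsum(slopes * diff(bp)))
    r <- approx(bp, v, xout = wl)$y
    r <- r + (1 - mean(r))
    list(wl = wl, r = r)
}

pwlSet <- function(slopes, ...) {
    s <- pwlSpectrum(slopes, ...)
    SpectralSet(matrix(s$r, dimnames = list(NULL, "pwl")), s$wl,
                normalized = TRUE)
}

# Reflectance whose first derivative is a prescribed function, built by
# trapezoidal integration (central differences then recover the derivative
# exactly wherever it is locally linear).
spectrumFromDerivative <- function(wl, d, r0 = 0.1) {
    r <- r0 + c(0, cumsum((d[-1] + d[-length(d)]) / 2 * diff(wl)))
    r
}

# A step spectrum taking given levels on given wavelength intervals
# (half-open [from, next)), for index micro-examples.
stepSpectrum <- function(breaks, levels, wl = 400:1050) {
    r <- levels[findInterval(wl, breaks)]
    r
}

# One denoised canopy-like normalized spectrum from the generator.
canopySpectrum <- function(cn = 12, species = "wheat") {
    cfg <- generatorConfig(noiseSD = 0, twoSpecies = FALSE)
    wl <- 400:1050
    r <- spectrumFromCN(cn, 1, species, cfg)
    r / mean(r)
}
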