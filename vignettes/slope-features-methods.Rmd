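---
title: "Monitoring leaf C/N from canopy spectra with segment-slope features"
author: "slopeCN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring leaf C/N from canopy spectra with segment-slope features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slopeCN)
```

## The problem

The ratio of leaf carbon to leaf nitrogen concentration (C/N = LCC/LNC,
dimensionless; LCC and LNC in g per 100 g dry mass) summarizes the
carbon–nitrogen metabolic balance of a cereal crop and is a useful indicator
for nutrient diagnosis. Because LCC varies only gently across a campaign
while LNC varies strongly, C/N tracks 1/LNC almost perfectly — which is what
makes optical estimation feasible at all: canopy reflectance responds
strongly to nitrogen (through chlorophyll) in the visible and red-edge
regions, and to leaf structure in the near infrared (NIR).

`slopeCN` implements a monitoring pipeline built on *segment-slope features*:
instead of reading reflectance at a handful of wavelengths (as classical
vegetation indices do), the normalized reflectance curve is divided at fixed
inflection wavelengths and the OLS slope of each segment is used as a
feature. Each slope aggregates dozens to hundreds of bands, which makes the
features robust to the band-to-band instability that plagues single-wavelength
indices.

## Preprocessing

Raw canopy reflectance on a 1 nm grid is processed in a fixed order:

1. **Truncation** to the 400–1050 nm working range (sub-400 nm bands are
   noise-dominated on field spectrometers; ~651 bands remain).
2. **Smoothing** with a five-band centered moving average. We read the
   five-band average as a *moving* average rather than non-overlapping
   blocks: the band count must stay near 650 for the segment fits to use
   every band, whereas block averaging would collapse the grid to ~130
   bands. Edges use the truncated window (no padding), the simplest contract
   that preserves band count.
3. **Mean normalization**: each spectrum is divided by its own mean over the
   retained bands, so every normalized spectrum has mean exactly 1.

Normalization is the load-bearing step: a multiplicative illumination factor
(cloud cover, sun angle) scales numerator and denominator alike, so the
normalized curve is invariant to illumination. This is asserted band-wise to
1e-9 in the tests, and normalization is idempotent. The mean is taken over
exactly the bands that survive truncation, nothing else.

## Segment-slope features

The default `segmentScheme()` places breakpoints at 400, 500, 550, 680, 760,
910, 960 and 1050 nm — the inflection points between the major peaks and
valleys of a cereal canopy spectrum — defining seven segments: `pb`
(400–500), `ge` (green edge, 500–550), `gprv` (green peak to red valley,
550–680), `re` (red edge, 680–760), `nir` (760–910), `nir2` (910–960) and
`nir3` (960–1050). For each segment, `Nr = k * lambda + b` is fitted by
unweighted OLS over *all* bands in the closed interval; the slope `k` (in
normalized reflectance per nm) is the feature `K_<segment>`.

Three conventions are fixed and documented rather than configurable
behaviour:

* **Closed intervals**: a breakpoint band contributes to both adjacent fits
  (segments share their vertices). At 1 nm resolution the alternative
  half-open convention changes slopes negligibly, but a single convention
  makes outputs reproducible.
* **Normalized reflectance only**: the slope API requires the normalized
  flag, since every slope analysis is defined on the normalized curve.
* **No wavelength rescaling**: the intercept `b` is reported but unused.

From the seven singles the package derives six ratios `K_x / K_re` and nine
combined features `(K_a + K_b) / (2 K_re)` with `a` in {pb, ge} — 22 features
in total. `K_re` is the natural denominator: the red-edge slope is strongly
positive for any green canopy and carries the most negative correlation with
C/N, so ratios against it amplify the signal and, being degree-0 in the
normalized curve, cancel any residual per-sample scale. A flat spectrum
(|K_re| < 1e-15) is a degenerate input and raises an error naming the
sample.

## Comparison indices

`indexRegistry()` lists the 22 classical chlorophyll/nitrogen indices used
for comparison, including derivative-based quantities: the maximum
first-derivative in the red edge (Dr), the ratio of derivative sums over the
red and blue edges (SDr/SDb, sums over 680–780 and 490–530 nm on the native
grid, no re-integration), and the red-edge position by linear extrapolation
(REP-le). For REP-le the first-derivative anchor wavelengths are 680/700
(far-red flank) and 725/760 (NIR flank), the standard anchors of the
linear-extrapolation method. Band lookups use the nearest grid wavelength
with ties toward the lower wavelength; range reflectances (GIT, WRNI's
minimum) are means/minima over the inclusive range.

Two transcription decisions: MTVI2 follows the standard published form
`1.5[1.2(R800 - R550) - 2.5(R670 - R550)]/sqrt((2 R800 + 1)^2 - (6 R800 -
5 sqrt(R670)) - 0.5)`, with a negative square-root argument reported as a
flagged missing value rather than a complex number; and "Red-edgeNDVI" is an
alias of NDRE (same formula family).

By default indices are computed on the same normalized spectra as the slope
features, for internal consistency; `indices.on_raw` in the run
configuration switches to smoothed raw reflectance. Scale-dependent indices
(those with additive constants, plus the degree-1 quantities MCARI and Dr)
then take different values — the registry records which of the 22 are
invariant to multiplicative scaling, and the tests assert the classification
in both directions. Note that REP-le and SDr/SDb *are* scale-invariant even
though they are derivative-based: scaling the spectrum scales both fitted
flank lines (or both derivative sums) by the same factor.

## Univariate model selection

Every feature is related to C/N by the best of three families: linear
`y = a + b x`, exponential `y = a exp(b x)` and logarithmic
`y = a + b ln x`. The exponential and logarithmic fits are linearized (OLS
on `ln y` and `ln x`), the standard agronomic practice and the only
closed-form reading of fitting those families; R² and RMSE are always
reported on the original response scale so the three families are
comparable, and RMSE uses denominator `n`. Selection takes the highest R²,
ties (ΔR² < 1e-9) broken by lower RMSE and then the fixed order linear <
logarithmic < exponential. Significance is `p < 0.01` everywhere (two-tailed
slope test of the linearized regression); non-significant best fits are
flagged, mirroring the dash convention of regression tables. Inapplicable
families (non-positive `y` for exponential, non-positive `x` for
logarithmic, n < 3) signal a skippable condition instead of aborting, so
selection simply proceeds over the remaining families.

Estimation models use the feature as predictor and C/N as response; the
sensitivity analysis (below) fits the opposite direction. Both directions
are recorded explicitly in the `ModelFit` object.

## Branch-and-bound subset selection

To combine several features in one multiple linear regression, the package
implements exact best-subset selection: for each size `k`,
`branchAndBound()` returns the subset with globally minimal residual sum of
squares among all `choose(p, k)` candidates. RSS at fixed `k` is the
criterion because it is the monotone quantity the bounding argument
requires: adding a variable never increases RSS, so the RSS of the model on
a search node's chosen-plus-remaining features bounds every subset in that
subtree from below, and subtrees that cannot beat the incumbent are pruned
without enumeration. A greedy forward pass seeds the incumbent and
candidates are ordered by single-feature strength so pruning bites early;
node counts are reported against the exhaustive total. Ties within 1e-9 of
RSS resolve lexicographically by candidate index, so results are
deterministic. The intercept is always included and never selectable.
`exhaustiveSearch()` (p ≤ 20) is kept as the independent optimality oracle,
and the test suite additionally checks both against a plain `lm.fit`
enumeration.

`subsetPath()` reports the per-size optima for `k = 1 … kMax`; nested
optimality makes in-sample R² non-decreasing and RMSE non-increasing along
the path, which is enforced. The package deliberately reports the whole
path and leaves the choice of `k` to the user; `stableK()` flags the
smallest `k` whose R² gain over `k − 1` drops below a threshold (default
0.01), the usual "curve flattens" reading. No information criteria or
cross-validation are involved — the fits are in-sample by design.
`applyModel()` evaluates a stored model on another feature table
(cross-species application); its evaluation R² is `1 − SSE/SST` on the
target table and may legitimately be negative out of domain.

## Noise-equivalent sensitivity

For a feature SF, `noiseEquivalent()` fits SF as a function of C/N
(direction reversed relative to estimation) and evaluates

    NE dC/N = RMSE(SF vs C/N) / |d(SF)/d(C/N)|

on a C/N grid (default 60 points over the observed range). The derivative
comes analytically from the fitted family (linear: `b`; exponential:
`a b exp(b x)`; logarithmic: `b/x`), so linear fits give a constant NE and
logarithmic fits an NE proportional to C/N. Lower NE means higher local
sensitivity, and because rescaling SF scales RMSE and derivative alike, NE
is invariant to affine rescaling of the feature — curves of different
features are directly comparable, and their crossings mark where the more
sensitive feature changes. Zero derivatives yield flagged infinities rather
than errors so curve comparisons still render. Which family backs each curve
is decided per feature by `bestFit()`.

## The synthetic generator

No field data ship with the package, so `generateDataset()` fabricates a
campaign with the statistical structure the method assumes. The chemistry
side draws C/N uniformly on 7.5–16.6 (the canonical spread of cereal
canopies for this problem) and LCC around 45 g/100 g with a 3 % CV, then
sets LNC = LCC/CN; consequently C/N and 1/LNC correlate above 0.95 while
C/N–LCC correlation stays below 0.3 in magnitude.

The spectral side is the simplest parametric family exhibiting every
segment the scheme names: a visible baseline, a Gaussian green peak at
550 nm, an inverted-Gaussian red well at 670 nm, a logistic red edge rising
to a gently tilted NIR plateau, and a small water dip near 960 nm. Every
shape parameter is an affine function of 1/CN (the chlorophyll proxy):
lower C/N means a darker visible region, deeper red well, steeper red edge,
flatter green flank and flatter NIR plateau. The constants were chosen once
so that the qualitative structure of real campaigns holds — K_re correlates
negatively with C/N, K_pb and K_ge positively, and the combined feature
(K_ge + K_nir)/(2 K_re) most strongly — and are documented in
`generatorConfig()`; they are calibration-free inventions, not estimates of
any field relationship, and absolute reflectance magnitudes are not claimed
to match real canopies (no radiative-transfer physics is involved).

Band noise is independent Gaussian (sd 0.003 reflectance units; the
smoothing stage exists to be exercised, so no autocorrelated noise is
simulated), and a per-sample illumination factor uniform on 0.5–1.2 is
applied last so normalization has something real to cancel. Reflectance is
clamped at 1e-6 after noise as a non-negativity guard; with the default
visible floor near 0.01–0.02 this is rare. In two-species mode (default:
120 wheat-like, 38 barley-like samples) barley spectra receive additive
baseline (+0.04) and NIR-tilt (+6e-5 per nm) offsets. An additive baseline
offset rescales all *normalized* slopes of a sample by a common factor, so
single slopes separate by species while ratio and combined features cancel
the offset exactly — the species-overlap structure that makes the combined
features usable as species-independent C/N indicators. This is a modelling
choice to realize that observed structure, not a claim about real canopies.

What passing tests on this generator do show: the pipeline's algebra,
invariances, optimality and sensitivity laws, and that the method recovers
the qualitative feature–C/N structure it presumes. What they cannot show:
performance on real canopies, where soil background, canopy architecture,
view geometry and water absorption introduce structure the generator does
not emulate. Numerical R²/RMSE from the generator are cleaner than any
field campaign would give and must not be read as field accuracies.

## Numerical choices and problem sizes

* Tolerances: normalized means to 1e-9; slope exactness on planted
  piecewise-linear spectra to 1e-12; OLS vs closed form to 1e-10;
  branch-and-bound vs enumeration to 1e-9; NE invariances to 1e-9.
* Tie-breaks: model families linear < logarithmic < exponential; subsets
  lexicographic by candidate index; band lookup ties toward the lower
  wavelength.
* Degenerate inputs: flat spectra error in slope extraction (named sample);
  degenerate index values become flagged missing entries at the table level
  but errors at the single-spectrum level; zero NE derivatives become
  flagged infinities.
* Problem sizes used by the test-suite and reproduction script: the
  study-scale campaign is n = 158 (120 + 38); subset-search checks run 200
  random instances at n = 50, p ≤ 12, k ≤ 6 plus 100 planted-support
  recovery trials; the end-to-end determinism workflow uses n = 60 and
  kMax = 4. These sizes keep the whole suite in the tens of seconds on one
  CPU while exercising every code path at full fidelity.
* All CSV/JSON output is serialized at 15 significant digits, which makes
  repeat runs from one seed byte-identical and write/read round trips
  accurate to 1e-12.

## Known limitations

* The exponential/logarithmic fits are linearized; an iterative
  nonlinear fit would weight residuals differently. The families exist for
  comparability of simple monotone forms, not as mechanistic models.
* The working range stops at 1050 nm; SWIR absorption features of nitrogen
  and carbon compounds (1400–2400 nm) are deliberately out of scope because
  they are masked by water absorption in fresh canopies.
* Breakpoints are fixed by the scheme, not estimated from the data;
  automatic inflection detection is out of scope.
* In-sample fitting throughout: no cross-validation, and subset-path R²
  always improves with k by construction — `stableK()` is a reading aid,
  not a model-selection criterion with guarantees.
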