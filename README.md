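# slopeCN

Estimating the leaf carbon-to-nitrogen ratio (C/N) of cereal crops — wheat
and barley — from canopy hyperspectral reflectance (400–1050 nm).

The C/N ratio (C/N = LCC/LNC, the ratio of leaf carbon to leaf nitrogen
concentration, both in g per 100 g dry mass) indicates the carbon–nitrogen
metabolic balance of a crop and is valuable for nutrient diagnosis. Because
leaf carbon varies little while leaf nitrogen varies strongly, C/N is
optically accessible through the same visible/red-edge/NIR reflectance
behaviour that makes canopy nitrogen retrievable.

Instead of reading reflectance at a few wavelengths, `slopeCN` works with
**segment-slope features**: the mean-normalized reflectance curve `Nr(λ)` is
divided at fixed inflection wavelengths (400, 500, 550, 680, 760, 910, 960,
1050 nm) and the OLS slope `K` of

    Nr = K·λ + b

over each closed segment becomes a feature — `K_pb`, `K_ge`, `K_gprv`,
`K_re`, `K_nir`, `K_nir2`, `K_nir3` — each aggregating dozens to hundreds of
bands. Six ratios `K_x/K_re` and nine combined features `(K_a + K_b)/(2·K_re)`
complete a 22-feature set; the red-edge slope `K_re` is the most negatively
C/N-correlated feature and the natural denominator. The package also
provides:

* the standard preprocessing chain (truncation, five-band smoothing, mean
  normalization `Nr_i = ρ_i / mean(ρ)`), which cancels multiplicative
  illumination differences exactly;
* 22 classical comparison indices (NDVI, MTCI, NDRE, MCARI/MTVI2, REP-le,
  Dr, SDr/SDb, …) in a queryable registry;
* univariate model selection over linear / exponential / logarithmic
  families, R²/RMSE on the original response scale, significance at p < 0.01;
* **exact branch-and-bound best-subset regression**: for each subset size k
  the globally RSS-optimal feature subset, with pruning based on the
  monotonicity of RSS under variable addition and an exhaustive-search
  oracle for verification;
* noise-equivalent sensitivity analysis,
  `NE ΔC/N = RMSE(SF vs C/N) / |d(SF)/d(C/N)|`, for comparing features on a
  common, scale-free footing;
* a parametric canopy-spectrum generator so the full pipeline is testable
  without field data.

Spectra live in a `SpectralSet`, a `SummarizedExperiment` extension
(wavelengths × samples, chemistry in `colData`).

## Worked example

```r
library(slopeCN)

## a study-scale synthetic campaign: 120 wheat-like + 38 barley-like samples
ds <- generateDataset(generatorConfig(nSamples = 158, seed = 1))
pp <- preprocessSpectra(ds)
pp
#> SpectralSet with 158 spectra x 651 bands
#>   wavelength range: 400 - 1050 nm
#>   normalized: TRUE
#>   sample data: species, LNC, LCC, CN

## 22 slope features per sample, joined with C/N
tab <- buildFeatureTable(pp)

## the best combined feature vs C/N
bestFit(tab$K_ge_plus_K_nir_over_2K_re, tab$CN)
#> ModelFit [exponential, feature->CN]: y = 3.382 exp(20.95 x)
#>   R2 = 0.8760  RMSE = 0.8541  p = 6.03e-78  (n = 158)

## exact best subsets of the 22 features, k = 1..4
X <- as.matrix(tab[, slopeFeatureNames()])
subsetPath(X, tab$CN, 4)
#> SubsetPath over k = 1 .. 4
#>  k                                     members      rss        r2      rmse
#>  1                              K_pb_over_K_re 27.55752 0.9703533 0.4176298
#>  2             K_re;K_pb_plus_K_nir_over_2K_re 22.07060 0.9762562 0.3737477
#>  3                    K_pb;K_re;K_pb_over_K_re 17.71081 0.9809465 0.3348040
#>  4 K_pb;K_nir3;K_pb_over_K_re;K_nir3_over_K_re 14.85900 0.9840145 0.3066664
#>   nodes explored: 6757 of 9108 exhaustive

## how finely the best feature resolves C/N across its range
noiseEquivalent(tab$K_ge_plus_K_nir_over_2K_re, tab$CN,
                featureName = "K_ge_plus_K_nir_over_2K_re")
#> SensitivityCurve for 'K_ge_plus_K_nir_over_2K_re' (logarithmic fit)
#>   NE dC/N over C/N 7.62-16.5: 0.544-1.18
```

Reading the numbers: the combined feature alone explains 88 % of the C/N
variance on this synthetic campaign with an RMSE of 0.85 C/N units; the
branch-and-bound subset of four features improves that to R² 0.984 while
exploring 6 757 of 9 108 possible least-squares fits; and the
noise-equivalent curve says a C/N change of roughly 0.5–1.2 units is
resolvable above the fit's residual noise, depending on where in the C/N
range the sample sits. Synthetic data are cleaner than field campaigns, so
these figures characterize the pipeline, not field accuracy.

A command-line front end wrapping the same functions is installed at
`system.file("scripts", "slopecn", package = "slopeCN")` with subcommands
`simulate`, `preprocess`, `features`, `indices`, `fit`, `bb-select`,
`apply`, `ne` and `indices-list`; all outputs are deterministic given the
seed and byte-identical across reruns.

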