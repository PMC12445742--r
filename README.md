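# conceptManifolds

Geometry of concept manifolds and few-shot classification error.

A *concept manifold* is the cloud of activity patterns (fMRI voxel
responses, encoding-model outputs, deep-network activations) evoked by
exemplars of one visual concept, viewed as points in activation space.
This package is for researchers who want to know *why* a linear
read-out separates two concepts well or badly in a given
representation: it estimates the small set of geometric properties
that, per the theory of few-shot prototype classification, determine
the error of an m-shot linear classifier, and it validates those
predictions against actual resampled classifiers.

For an ordered concept pair (a, b), with centroid difference
Δx = (x₀ᵃ − x₀ᵇ)/Rₐ and radius-weighted principal direction matrices
Uᵃ, Uᵇ (columns rᵢuᵢ/Rₐ), the package computes

* geometric **Signal** S = ‖Δx‖², **Bias** b = R_b²/R_a² − 1,
* **Noise–Signal Overlaps** Nᵃ = ‖Δx·Uᵃ‖², Nᵇ = ‖Δx·Uᵇ‖²,
  **Noise–Noise Overlap** Nᵃᵇ = ‖(Uᵃ)ᵀUᵇ‖²_F,
* participation-ratio **Dimensionality** Dₐ = Rₐ⁴/Σᵢrᵢ⁴,

and the geometric signal-to-noise ratio

    SNR(m) = ½ (S + b/m) / sqrt( (Dₐ⁻¹ + Nᵇ + Nᵃᵇ)/m + Nᵃ )

whose Gaussian tail H(SNR(m)) predicts the m-shot error. Around this
core sit: the nested-resampling empirical protocol (16×16 folds,
geometry and error as paired fold observations), random
subspace/projection embedding with convergence sweeps, a synthetic
manifold generator with analytic ground truth and a trial-to-trial
measurement-noise model, and second-order analyses (log-linear Overlap
model, iso-SNR surfaces in the Signal–Dimensionality plane,
permutation-tested property correlations, concept-hierarchy distances).

## Worked example

Two synthetic concepts in a 100-dimensional activation space, 580
exemplars each:

```r
library(conceptManifolds)

spec <- manifoldSpec(ambientDim = 100,
                     centers = cbind(food  = rep(0, 100),
                                     sport = c(2.2, rep(0, 99))),
                     spectra = list(c(4, 2, 1, 0.5), c(3, 2, 1.5)),
                     exemplarCount = 580, seed = 7)
ds <- sampleManifolds(spec, seed = 1)
A  <- estimateManifold(ds, "food")
B  <- estimateManifold(ds, "sport")
pairGeometry(A, B, m = 5)
#> PairGeometry ('food' relative to 'sport'), m = 5
#>   S = 0.604  b = -0.1228  D_a = 2.734
#>   N^a = 0.003521  N^b = 0.002747  N^ab = 0.01008  N(m) = 0.006087
#>   SNR(m) = 1.0292  predicted error = 0.1517
```

The 'food' manifold sits 0.6 squared-radius units from 'sport', is
slightly larger than it (negative Bias), uses ~2.7 effective
directions, and the overlaps are small — so the theory predicts a
5-shot error of 15.2% for food-vs-sport. The empirical protocol agrees:

```r
fs <- fewShotErrorProtocol(ds, m = 5, nOuter = 8, nInner = 8, seed = 11)
round(errorMean(fs), 4)
#>         food  sport
#> food      NA 0.1887
#> sport 0.0601     NA
mean(foldGeometry(fs)$predicted_error)
#> [1] 0.1263
```

Measured 5-shot errors are 18.9% (food vs sport) and 6.0% (sport vs
food — the pair is ordered and asymmetric); their mean, 12.4%, matches
the mean fold-level prediction of 12.6%.

A full run over many concepts — geometry tables, few-shot matrices,
log-linear Overlap fit, manifest — is one call:
`runPipeline(list(spec = "spec.json", outDir = "out", seed = 1))`.

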