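---
title: "Concept manifold geometry and few-shot classification error"
author: "conceptManifolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept manifold geometry and few-shot classification error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# The model

A *concept manifold* is the cloud of activity patterns — fMRI voxel
responses, encoding-model outputs, or network-unit activations — evoked
by exemplars of one visual concept, viewed as points in the
V-dimensional activation space. Whether a simple linear read-out can
tell two concepts apart is a question about the geometry of the two
clouds: how far apart their centers are, how large and how anisotropic
each cloud is, and how the clouds' principal axes align with each other
and with the line joining the centers.

`conceptManifolds` implements the geometric theory of few-shot
prototype classification for pairs of such manifolds. For a concept $a$
with exemplar matrix $X^a$ (P exemplars by V units) we estimate the
centroid $x_0^a$ and the PCA spectrum of the centered data, defining
radii $r_i^a$ (standard deviations along principal directions $u_i^a$),
the squared total radius $R_a^2 = \sum_i (r_i^a)^2$, and the
participation-ratio Dimensionality
$D_a = R_a^4 / \sum_i (r_i^a)^4$ — the effective number of
variance-carrying directions (V for an isotropic cloud, 1 for a
needle).

For an ordered pair $(a, b)$, with $\Delta x = (x_0^a - x_0^b)/R_a$ and
radius-weighted direction matrices $U^a, U^b$ (columns $r_i u_i / R_a$,
both normalized by the reference manifold's radius), the theory's
quantities are

* geometric **Signal** $S_{a,b} = \lVert\Delta x\rVert^2$,
* **Bias** $b_{a,b} = R_b^2 / R_a^2 - 1$,
* **Noise–Signal Overlaps** $N^a_{a,b} = \lVert\Delta x U^a\rVert^2$,
  $N^b_{a,b} = \lVert\Delta x U^b\rVert^2$,
* **Noise–Noise Overlap**
  $N^{ab}_{a,b} = \lVert (U^a)^\top U^b \rVert_F^2$,

combined in the geometric signal-to-noise ratio (keeping only terms
linear in $1/m$)

$$\mathrm{SNR}_{a,b}(m) \;=\;
  \frac{\tfrac12\!\left(S_{a,b} + b_{a,b}/m\right)}
       {\sqrt{\left(D_a^{-1} + N^b_{a,b} + N^{ab}_{a,b}\right)/m
              + N^a_{a,b}}}.$$

An $m$-shot prototype classifier (prototypes = means of $m$ training
exemplars per concept; test patterns assigned to the nearer prototype)
then misclassifies held-out concept-$a$ exemplars at rate
$H(\mathrm{SNR}(m))$, where $H$ is the upper tail of the standard
normal distribution. All pairwise quantities are *ordered* — they
describe $a$ relative to $b$ — and in general
$\mathrm{SNR}_{a,b} \neq \mathrm{SNR}_{b,a}$.

```{r}
library(conceptManifolds)

spec <- manifoldSpec(ambientDim = 100,
                     centers = cbind(food  = rep(0, 100),
                                     sport = c(2.2, rep(0, 99))),
                     spectra = list(c(4, 2, 1, 0.5), c(3, 2, 1.5)),
                     exemplarCount = 580, seed = 7)
ds <- sampleManifolds(spec, seed = 1)
A <- estimateManifold(ds, "food")
B <- estimateManifold(ds, "sport")
pairGeometry(A, B, m = 5)
```

## Conventions that the estimates depend on

**Spectrum normalization.** Radii are defined on the variance scale:
$r_i^2$ is the $i$-th eigenvalue of the covariance $X_c^\top X_c / P$
of the centered data (equivalently $r_i^2 P$ is the squared singular
value). This is the scale on which the SNR expression predicts
empirical error and on which estimates converge to the generator's
population values as $P \to \infty$; any rescaling would leave $D$
untouched but destroy both properties. All $\min(P-1, V)$ PCA
components are retained — no variance-threshold truncation.

**Degenerate input.** A concept whose exemplars are all identical has
zero total radius; it raises an error from `estimateManifold` and is
excluded (with a warning) by `geometryGrid`, rather than being assigned
$D = 0$.

**Gaussian tail.** `gaussianTailError` is
$H(z) = \tfrac12(1 - \mathrm{erf}(z/\sqrt2))$, i.e.
`pnorm(z, lower.tail = FALSE)`; $H(0) = 1/2$ and $H(z) + H(-z) = 1$.

**Tie-breaking.** A test pattern exactly equidistant from both
prototypes is assigned to the reference concept; ties have measure zero
for continuous data, so the convention only matters for constructed
inputs.

**Orthonormality tolerance.** Validity checks on direction matrices and
bases use a 1e-8 relative tolerance.

# The empirical protocol

`fewShotErrorProtocol` measures error the way the theory is validated:
each outer fold splits every concept's exemplars into a ~90% group, on
which the pairwise geometry is computed, and a ~10% holdout
(`floor(0.10 P)`, floored at $m+1$ rows); each inner draw takes $m$
holdout exemplars per concept as the prototype sample and classifies
the remaining holdout exemplars for every ordered pair. Sixteen inner
draws are averaged, and mean and standard deviation are taken across
sixteen outer folds (both counts configurable). Because geometry and
error come from the same outer fold, fold-level SNR and error are
paired observations. When trial repeats are present they are averaged
into one row per exemplar *before* splitting, so no trial of a test
exemplar can leak into the geometry or prototype side. A master seed
spawns one independent stream per outer fold, making runs reproducible
and fold-order independent.

```{r}
fs <- fewShotErrorProtocol(ds, m = 5, nOuter = 8, nInner = 8, seed = 11)
errorMean(fs)
mean(foldGeometry(fs)$predicted_error)
```

The across-fold mean error sits on the theory curve: compare
`errorMean` with `gaussianTailError` of the fold-mean SNR.

# Random embedding

High-dimensional populations are embedded before analysis:
`randomSubspace` samples units without replacement (clamped, with a
warning, at the ambient dimension) and `randomProject` applies a dense
Gaussian map with i.i.d. $N(0, 1/d)$ entries — the standard
Johnson–Lindenstrauss choice, preserving squared norms in expectation.
The projection law is the package's choice; nothing in the geometry
depends on it beyond rotational symmetry and the $1/d$ variance.
`convergenceSweep` tabulates mean SNR and Signal over a grid of
(subspace, projection) dimensions, plus each as a fraction of its grid
maximum, and skips the projection whenever the target dimension is not
below the current one — so the largest grid point reproduces the
unswept estimate exactly. For manifolds with $D \lesssim 30$, projecting
to 300 dimensions changes across-pair mean Signal, Dimensionality and
SNR by well under 10%; a single pair's Signal, however, carries an
irreducible Johnson–Lindenstrauss fluctuation of about
$\sqrt{2/d} \approx 8\%$ at $d = 300$, which is why convergence is
judged on across-pair means (and, in the tests, additionally averaged
over repeated projections, mirroring the repeated-embedding practice
for reporting stable estimates).

# The synthetic generator

`manifoldSpec` + `sampleManifolds` generate per-concept Gaussian clouds
$x = c + B\,\mathrm{diag}(\sqrt\lambda)\,z$ with low-rank anisotropic
covariance in a common ambient space — the statistical structure of
denoised encoding-model outputs. Random bases are materialized at spec
construction (QR of a seeded Gaussian matrix), so
`groundTruthGeometry` can evaluate the same pairwise formulas on the
population parameters ($r_i^2 = \lambda_i$) and serve as the recovery
oracle: estimates converge to it as $P$ grows.

What the generator deliberately does **not** emulate: non-Gaussian
cloud shape (curved or multimodal manifolds), heavy-tailed unit noise,
spatial voxel correlations from the hemodynamic point-spread, and
stimulus-driven dependence between concepts (an image belonging to two
concepts). Passing recovery tests therefore demonstrate correctness of
the estimators under the theory's own assumptions, not robustness to
every property of real fMRI data.

**Measurement noise.** `addMeasurementNoise` replicates each exemplar
`nTrials` times and adds zero-mean Gaussian noise whose mean per-unit
variance is (signal variance across exemplars) / `measurementSnr`,
matching the measurement-SNR convention (variance of average activity
across images over average noise variance). Uncorrelated mode uses
independent unit noise; correlated mode draws a Wishart
($V$ degrees of freedom) covariance rescaled to the same mean diagonal
— the correlated structure is otherwise unconstrained, so an
uninformative random choice is used. Signal is fixed per exemplar,
noise is fresh per trial. `trialAverage` collapses `nSamples`
seed-selected trials per exemplar, cutting the effective noise variance
by `nSamples`.

`noiseDistortionExperiment` tabulates estimated versus asymptotic
geometry over a grid of measurement SNRs, noise modes and averaging
depths. Its characteristic signatures: measurement noise *inflates*
Dimensionality while *deflating* geometric SNR and Signal, and deeper
trial averaging moves every estimate toward its asymptote. Both
statements concern the regime where measurement noise dominates the
estimation error; the experiment therefore uses large exemplar counts
(the shipped analyses use $P = 8000$ per concept at $V = 60$), because
with small $P$ the finite-sample bias — upward on Signal and SNR — can
accidentally cancel the noise bias and make a noisier estimate land
nearer the asymptote. That cancellation is a property of small samples,
not of trial averaging.

# Covariation analyses

Across concept pairs, the combined Overlap
$N(m) = (N^b + N^{ab})/m + N^a$ is modeled log-linearly in Signal and
Dimensionality, $\log N(m) = \alpha \log S + \beta \log D + \gamma$
(natural logarithms — the base only rescales coefficients), by ordinary
least squares; pairs with nonpositive $S$, $D$ or $N(m)$ are excluded
with a warning since their logarithm is undefined. The single-predictor
($\log S$ only) $R^2$ is reported alongside for comparison.
`snrSurface` substitutes the fitted $\hat N(m) = e^\gamma S^\alpha
D^\beta$ into the SNR expression with the Bias held at a constant
(typically its per-dataset mean, the Bias being essentially independent
of the other properties), giving SNR as a function of $(S, D)$ alone;
its contour levels are the iso-SNR lines, slightly curved in log-log
coordinates unless $\beta = -2\alpha$.

```{r}
gg <- geometryGrid(ds, m = 5)
fit <- fitLogLinearOverlap(gg$pairs)
fit
```

`pearsonPermutation` attaches a two-sided permutation p-value to a
Pearson correlation using the add-one estimator
$p = (1 + \#\{|r_\pi| \ge |r_{obs}|\})/(n_\pi + 1)$, which can never be
zero and is valid (type-I rate at most nominal up to Monte-Carlo
error). `propertyCorrelationSuite` applies it to all pairs of
{SNR, Signal, Bias, Overlap, Dimensionality}, either across levels
(ROIs/layers) after within-level averaging or across pooled concept
pairs; permutations pool all observations (a grouping hook would be
needed for stratified permutation, which is out of scope here).
Constant properties (e.g. a fixed Bias) yield `NA` with a warning
rather than an error. `hierarchyPathDistance` computes hop counts on a
user-supplied undirected concept hierarchy via `igraph`, and
`accuracyVsDistance` bins few-shot success by hop count (one bin per
integer distance) and reports the overall success–distance correlation.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on generated
data at sizes chosen to make Monte-Carlo error small relative to the
assertion bands while remaining desk-scale: 20 spherical pairs with
$P = 580$ exemplars at $V = 100$ under 16×16 folds for the
theory-validation sweep; 20 replicates of five rank-5…30 manifolds in
10,000 ambient dimensions projected to 300 (averaged over 5
projections) for projection invariance; $P = 8000$, $V = 60$ for the
measurement-noise experiment; 1,000 null replicates of $n = 50$ with
1,000 permutations each for permutation calibration. Within-package
seeds are spawned from a single master seed via a seeded draw of
sub-seeds, so nested loops are reproducible and order-independent.

Known limitations: only pairwise (not $n$-way) classifiers, matching
the theory; only terms linear in $1/m$ in the SNR; dense Gaussian
projections only; and the generator's Gaussian assumption above. For
extremely anisotropic spectra the participation ratio approaches 1 and
the normal approximation behind $H$ degrades at large SNR — empirical
errors there are predicted to be (and are) essentially zero, so the
absolute deviation stays small even where the relative one does not.
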