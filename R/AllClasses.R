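#' @import methods
#' @importFrom stats cor pnorm rnorm sd var aggregate lm coef
#' @importFrom utils head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

#' ActivitySet: labeled exemplar-by-unit activity patterns
#'
#' The universal input container of the package: a matrix of activity
#' patterns (fMRI voxel betas, encoding-model outputs, network unit
#' activations) with one pattern per exemplar presentation and one column
#' per unit, plus a concept label per pattern and an optional trial
#' identifier grouping repeated presentations of the same exemplar.
#'
#' Internally the class extends
#' \linkS4class{SummarizedExperiment}: the \code{"activity"} assay stores
#' units in rows and exemplar presentations in columns (the Bioconductor
#' convention), while \code{\link{activityPatterns}} returns the
#' exemplar-by-unit orientation used throughout the geometry functions.
#' Column metadata holds \code{concept} and, when present, \code{trial}.
#'
#' @section Validity:
#' \itemize{
#'   \item all activity values are finite (no \code{NA}/\code{NaN});
#'   \item every exemplar carries a non-empty concept label;
#'   \item rows sharing a \code{trial} identifier share the same label.
#' }
#'
#' @seealso \code{\link{ActivitySet}} (constructor),
#'   \code{\link{readActivityDataset}}, \code{\link{estimateManifold}}
#' @name ActivitySet-class
#' @aliases ActivitySet-class
#' @exportClass ActivitySet
setClass("ActivitySet", contains = "SummarizedExperiment")

setValidity("ActivitySet", function(object) {
    a <- SummarizedExperiment::assay(object, "activity")
    if (!is.numeric(a))
        return("activity assay must be numeric")
    if (any(!is.finite(a)))
        return("activity assay contains missing or non-finite values")
    cd <- SummarizedExperiment::colData(object)
    if (!("concept" %in% colnames(cd)))
        return("colData must contain a 'concept' column")
    lab <- as.character(cd$concept)
    if (any(is.na(lab)) || any(!nzchar(lab)))
        return("every exemplar must have a non-empty concept label")
    if ("trial" %in% colnames(cd)) {
        tr <- cd$trial
        if (any(is.na(tr)))
            return("trial identifiers must not be missing")
        bad <- vapply(split(lab, tr), function(l) length(unique(l)) > 1L,
                      logical(1))
        if (any(bad))
            return("rows sharing a trial identifier must share one label")
    }
    TRUE
})

#' ManifoldSummary: one concept's estimated manifold geometry
#'
#' Holds the centroid, the radii spectrum (standard deviations along the
#' principal directions), the orthonormal principal directions, the squared
#' total radius \eqn{R_a^2 = \sum_i (r_i^a)^2} and the participation-ratio
#' Dimensionality \eqn{D_a = R_a^4 / \sum_i (r_i^a)^4} of a single concept
#' manifold.
#'
#' @slot concept concept label.
#' @slot centroid length-V centroid of the exemplar cloud.
#' @slot radii nonincreasing, nonnegative radii \eqn{r_i}.
#' @slot directions V-by-k orthonormal matrix of principal directions.
#' @slot totalRadiusSq \eqn{R^2 = \sum_i r_i^2}.
#' @slot dimensionality participation ratio of the variance spectrum.
#' @slot nExemplars number of exemplars the estimate is based on.
#' @seealso \code{\link{estimateManifold}}, \code{\link{pairGeometry}}
#' @exportClass ManifoldSummary
setClass("ManifoldSummary",
    representation(concept = "character",
                   centroid = "numeric",
                   radii = "numeric",
                   directions = "matrix",
                   totalRadiusSq = "numeric",
                   dimensionality = "numeric",
                   nExemplars = "integer"))

setValidity("ManifoldSummary", function(object) {
    r <- object@radii
    U <- object@directions
    if (any(r < 0)) return("radii must be nonnegative")
    if (is.unsorted(rev(r), strictly = FALSE))
        return("radii must be nonincreasing")
    if (length(object@centroid) != nrow(U))
        return("centroid length must match the ambient dimension")
    if (length(r) != ncol(U))
        return("one radius per principal direction required")
    g <- crossprod(U)
    if (max(abs(g - diag(ncol(U)))) > 1e-8 * max(1, max(abs(g))))
        return("principal directions must be orthonormal (1e-8 relative)")
    if (!isTRUE(all.equal(object@totalRadiusSq, sum(r^2))))
        return("totalRadiusSq must equal the sum of squared radii")
    nnz <- sum(r > 0)
    if (object@dimensionality < 1 - 1e-8 ||
        object@dimensionality > nnz + 1e-8)
        return("dimensionality must lie in [1, #nonzero radii]")
    TRUE
})

#' PairGeometry: pairwise geometric quantities for an ordered concept pair
#'
#' All quantities of the few-shot theory for the ordered pair (a, b):
#' geometric Signal \eqn{S_{a,b}}, Bias \eqn{b_{a,b}}, Noise-Signal
#' Overlaps \eqn{N^a_{a,b}}, \eqn{N^b_{a,b}}, Noise-Noise Overlap
#' \eqn{N^{ab}_{a,b}}, the combined Overlap
#' \eqn{N(m) = (N^b + N^{ab})/m + N^a}, the geometric SNR(m) and the
#' predicted m-shot error \eqn{H(SNR(m))}. All elements describe concept a
#' relative to concept b; the pair is ordered and the quantities are in
#' general asymmetric.
#'
#' @slot conceptA,conceptB labels of the ordered pair.
#' @slot m shot count.
#' @slot signal geometric Signal (squared normalized centroid distance).
#' @slot bias geometric Bias \eqn{R_b^2/R_a^2 - 1}.
#' @slot overlapA,overlapB Noise-Signal Overlaps.
#' @slot overlapAB Noise-Noise Overlap.
#' @slot combinedOverlap combined Overlap N(m).
#' @slot snr geometric SNR(m).
#' @slot predictedError predicted m-shot error, \eqn{H(SNR(m))}.
#' @slot dimensionalityA Dimensionality of the reference concept a.
#' @seealso \code{\link{pairGeometry}}, \code{\link{gaussianTailError}}
#' @exportClass PairGeometry
setClass("PairGeometry",
    representation(conceptA = "character", conceptB = "character",
                   m = "integer",
                   signal = "numeric", bias = "numeric",
                   overlapA = "numeric", overlapB = "numeric",
                   overlapAB = "numeric", combinedOverlap = "numeric",
                   snr = "numeric", predictedError = "numeric",
                   dimensionalityA = "numeric"))

setValidity("PairGeometry", function(object) {
    if (object@signal < 0) return("signal must be nonnegative")
    if (min(object@overlapA, object@overlapB, object@overlapAB) < 0)
        return("overlaps must be nonnegative")
    nm <- (object@overlapB + object@overlapAB) / object@m + object@overlapA
    if (!isTRUE(all.equal(object@combinedOverlap, nm)))
        return("combinedOverlap must equal (N^b + N^ab)/m + N^a")
    if (!isTRUE(all.equal(object@predictedError,
                          pnorm(object@snr, lower.tail = FALSE))))
        return("predictedError must equal the Gaussian tail of the SNR")
    TRUE
})

#' FewShotResult: empirical m-shot error matrices
#'
#' Mean and across-outer-fold standard deviation of the empirical m-shot
#' prototype-classifier error for every ordered concept pair, as produced
#' by the nested resampling protocol of
#' \code{\link{fewShotErrorProtocol}}. Entry (a, b) is the fraction of
#' held-out concept-a exemplars misclassified against concept b; the
#' diagonal is undefined and stored as \code{NA}.
#'
#' @slot errorMean,errorStd concept-by-concept matrices.
#' @slot m shot count.
#' @slot nOuter,nInner fold counts of the nested protocol.
#' @slot holdoutFraction fraction of exemplars held out per outer fold.
#' @slot seed master seed of the run.
#' @slot foldGeometry per-outer-fold pairwise geometry (data.frame), so
#'   that empirical error and geometric SNR are paired observations.
#' @exportClass FewShotResult
setClass("FewShotResult",
    representation(errorMean = "matrix", errorStd = "matrix",
                   m = "integer", nOuter = "integer", nInner = "integer",
                   holdoutFraction = "numeric", seed = "integer",
                   foldGeometry = "data.frame"))

setValidity("FewShotResult", function(object) {
    em <- object@errorMean
    es <- object@errorStd
    if (!identical(dim(em), dim(es)))
        return("errorMean and errorStd must share a shape")
    if (!identical(dimnames(em), dimnames(es)))
        return("errorMean and errorStd must share concept ordering")
    off <- em[row(em) != col(em)]
    if (any(!is.na(off) & (off < 0 | off > 1)))
        return("error entries must lie in [0, 1]")
    TRUE
})

#' ManifoldSpec: ground-truth generative description of concept manifolds
#'
#' A fully explicit generative model for synthetic concept manifolds: for
#' each concept a center, an intrinsic variance spectrum
#' \eqn{\lambda_i} and an orthonormal basis of intrinsic directions in a
#' common V-dimensional ambient space. Exemplars are Gaussian:
#' \eqn{x = c + B \, diag(\sqrt{\lambda}) \, z}, \eqn{z \sim N(0, I)}.
#' Because every basis is materialized at construction time, the analytic
#' (population) geometry of any concept pair is available through
#' \code{\link{groundTruthGeometry}} and serves as the recovery oracle for
#' the estimation pipeline.
#'
#' @slot ambientDim ambient dimension V.
#' @slot conceptNames concept labels.
#' @slot centers V-by-C matrix of concept centers.
#' @slot spectra list of nonnegative intrinsic variances, one per concept.
#' @slot bases list of V-by-k orthonormal basis matrices.
#' @slot exemplarCount exemplars to draw per concept.
#' @seealso \code{\link{manifoldSpec}}, \code{\link{sampleManifolds}},
#'   \code{\link{addMeasurementNoise}}
#' @exportClass ManifoldSpec
setClass("ManifoldSpec",
    representation(ambientDim = "integer", conceptNames = "character",
                   centers = "matrix", spectra = "list", bases = "list",
                   exemplarCount = "integer"))

setValidity("ManifoldSpec", function(object) {
    V <- object@ambientDim
    C <- length(object@conceptNames)
    if (ncol(object@centers) != C || nrow(object@centers) != V)
        return("centers must be an ambientDim-by-nConcepts matrix")
    if (length(object@spectra) != C || length(object@bases) != C ||
        length(object@exemplarCount) != C)
        return("spectra, bases, exemplarCount must have one entry per concept")
    for (i in seq_len(C)) {
        lam <- object@spectra[[i]]
        B <- object@bases[[i]]
        if (any(lam < 0)) return("spectra must be nonnegative")
        if (nrow(B) != V || ncol(B) != length(lam))
            return("each basis must be ambientDim-by-length(spectrum)")
        g <- crossprod(B)
        if (max(abs(g - diag(ncol(B)))) > 1e-8)
            return("bases must be orthonormal")
    }
    if (any(object@exemplarCount < 1L))
        return("exemplarCount must be positive")
    TRUE
})

#' LogLinearFit: log-linear model of the combined Overlap
#'
#' Coefficients of the regression
#' \eqn{\log N(m) = \alpha \log S + \beta \log D + \gamma}
#' fitted across concept pairs, with the coefficient of determination and,
#' for comparison, the R-squared of the single-predictor (log S only)
#' regression.
#'
#' @slot alpha,beta,gamma fitted coefficients (natural logarithms).
#' @slot coefSe standard errors, named (gamma, alpha, beta).
#' @slot rSquared coefficient of determination of the two-predictor fit.
#' @slot rSquaredSignalOnly R-squared of the log S-only regression.
#' @slot m shot count the Overlap was computed at.
#' @slot nPoints pairs entering the fit.
#' @slot nExcluded pairs dropped for nonpositive S, D or N(m).
#' @seealso \code{\link{fitLogLinearOverlap}}, \code{\link{snrSurface}}
#' @exportClass LogLinearFit
setClass("LogLinearFit",
    representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                   coefSe = "numeric", rSquared = "numeric",
                   rSquaredSignalOnly = "numeric", m = "integer",
                   nPoints = "integer", nExcluded = "integer"))

setValidity("LogLinearFit", function(object) {
    if (object@rSquared < 0 || object@rSquared > 1)
        return("rSquared must lie in [0, 1]")
    TRUE
})

#' PermutationCorrelation: Pearson correlation with permutation p-value
#'
#' @slot rho observed Pearson correlation.
#' @slot pValue two-sided permutation p-value (add-one estimator, so
#'   bounded below by 1/(nPermutations + 1)).
#' @slot nPermutations number of label permutations drawn.
#' @seealso \code{\link{pearsonPermutation}}
#' @exportClass PermutationCorrelation
setClass("PermutationCorrelation",
    representation(rho = "numeric", pValue = "numeric",
                   nPermutations = "integer"))

setValidity("PermutationCorrelation", function(object) {
    if (object@pValue <= 0 || object@pValue > 1)
        return("pValue must lie in (0, 1]")
    if (object@pValue < 1 / (object@nPermutations + 1) - 1e-12)
        return("pValue cannot undercut the add-one lower bound")
    TRUE
})
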