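#' Construct a ManifoldSpec
#'
#' Builds an explicit generative description of Gaussian concept
#' manifolds: per-concept centers, intrinsic variance spectra
#' \eqn{\lambda_i} and orthonormal intrinsic bases in a common ambient
#' space. Bases given as the token \code{"random"} are materialized
#' immediately (QR of a seeded Gaussian matrix), so the returned spec is
#' fully explicit and its analytic geometry is deterministic.
#'
#' @param ambientDim ambient dimension V.
#' @param centers V-by-C matrix of concept centers (column names become
#'   concept names), or a list of length-V vectors.
#' @param spectra list of nonnegative variance spectra, one per concept
#'   (recycled if a single vector is given).
#' @param bases list of V-by-k orthonormal matrices, or the token
#'   \code{"random"} (default) to draw uniformly random bases.
#' @param exemplarCount exemplars per concept (recycled).
#' @param conceptNames optional explicit concept names.
#' @param seed required when any basis is \code{"random"}.
#' @return a \linkS4class{ManifoldSpec}.
#' @examples
#' spec <- manifoldSpec(ambientDim = 50,
#'                      centers = cbind(a = rep(0, 50), b = rep(0.3, 50)),
#'                      spectra = list(c(4, 2, 1), c(4, 2, 1)), seed = 1)
#' spec
#' @export
manifoldSpec <- function(ambientDim, centers, spectra, bases = "random",
                         exemplarCount = 100L, conceptNames = NULL,
                         seed = NULL) {
    ambientDim <- .assertCount(ambientDim, "ambientDim")
    if (is.list(centers))
        centers <- do.call(cbind, centers)
    centers <- as.matrix(centers)
    C <- ncol(centers)
    if (nrow(centers) != ambientDim)
        stop("centers must have ambientDim rows")
    if (is.null(conceptNames))
        conceptNames <- colnames(centers)
    if (is.null(conceptNames))
        conceptNames <- paste0("concept", seq_len(C))
    if (!is.list(spectra))
        spectra <- rep(list(as.numeric(spectra)), C)
    if (length(spectra) != C)
        stop("one spectrum per concept is required")
    spectra <- lapply(spectra, as.numeric)
    if (identical(bases, "random")) {
        if (is.null(seed))
            stop("a seed is required to materialize random bases")
        bseeds <- spawnSeeds(seed, C)
        bases <- lapply(seq_len(C), function(i) {
            k <- length(spectra[[i]])
            if (k > ambientDim)
                stop("spectrum longer than the ambient dimension")
            withSeed(bseeds[i],
                qr.Q(qr(matrix(rnorm(ambientDim * k), ambientDim, k))))
        })
    }
    if (length(bases) != C)
        stop("one basis per concept is required")
    # sort each spectrum nonincreasing, permuting basis columns to match
    for (i in seq_len(C)) {
        o <- order(spectra[[i]], decreasing = TRUE)
        spectra[[i]] <- spectra[[i]][o]
        bases[[i]] <- bases[[i]][, o, drop = FALSE]
    }
    exemplarCount <- as.integer(rep_len(exemplarCount, C))
    colnames(centers) <- conceptNames
    new("ManifoldSpec", ambientDim = ambientDim,
        conceptNames = conceptNames, centers = centers,
        spectra = spectra, bases = bases, exemplarCount = exemplarCount)
}

setMethod("show", "ManifoldSpec", function(object) {
    cat(sprintf("ManifoldSpec: %d concepts in %d ambient dimensions\n",
                length(object@conceptNames), object@ambientDim))
    for (i in seq_along(object@conceptNames)) {
        lam <- object@spectra[[i]]
        cat(sprintf("  '%s': k = %d, sum(lambda) = %.4g, D = %.3f, P = %d\n",
                    object@conceptNames[i], length(lam), sum(lam),
                    if (sum(lam^2) > 0) sum(lam)^2 / sum(lam^2) else NA,
                    object@exemplarCount[i]))
    }
})

#' @rdname ActivitySet-accessors
#' @export
setMethod("conceptNames", "ManifoldSpec", function(x) x@conceptNames)

#' Sample noiseless exemplars from a ManifoldSpec
#'
#' Draws, for each concept, \code{P} exemplars
#' \eqn{x = c + B \, diag(\sqrt{\lambda}) \, z}, \eqn{z \sim N(0, I_k)}.
#' This emulates the statistical structure of encoding-model outputs:
#' per-concept Gaussian clouds with low-rank anisotropic covariance in a
#' high-dimensional ambient space.
#'
#' @param spec a \linkS4class{ManifoldSpec}.
#' @param exemplarCount optional override of the spec's per-concept
#'   exemplar counts (recycled).
#' @param seed RNG seed.
#' @return an \linkS4class{ActivitySet} of noiseless exemplars.
#' @export
sampleManifolds <- function(spec, exemplarCount = NULL, seed) {
    stopifnot(is(spec, "ManifoldSpec"))
    P <- if (is.null(exemplarCount)) spec@exemplarCount else
        as.integer(rep_len(exemplarCount, length(spec@conceptNames)))
    withSeed(seed, {
        blocks <- lapply(seq_along(spec@conceptNames), function(i) {
            lam <- spec@spectra[[i]]
            B <- spec@bases[[i]]
            Z <- matrix(rnorm(P[i] * length(lam)), P[i], length(lam))
            sweep(Z, 2L, sqrt(lam), `*`) %*% t(B) +
                matrix(spec@centers[, i], P[i], spec@ambientDim,
                       byrow = TRUE)
        })
        ActivitySet(do.call(rbind, blocks),
                    rep(spec@conceptNames, P))
    })
}

# population ManifoldSummary straight from the spec
.summaryFromSpec <- function(spec, concept) {
    i <- match(concept, spec@conceptNames)
    if (is.na(i))
        stop("concept '", concept, "' not in the spec")
    lam <- spec@spectra[[i]]
    new("ManifoldSummary", concept = concept,
        centroid = spec@centers[, i],
        radii = sqrt(lam),
        directions = spec@bases[[i]],
        totalRadiusSq = sum(lam),
        dimensionality = sum(lam)^2 / sum(lam^2),
        nExemplars = spec@exemplarCount[i])
}

#' Population (ground-truth) manifold geometry of a spec
#'
#' The analytic twin of the estimation pipeline: evaluates the same
#' pairwise formulas on the spec's centers, spectra and bases, with
#' population radii \eqn{r_i^2 = \lambda_i}, so that estimates from
#' \code{\link{estimateManifold}} converge to these values as the number
#' of exemplars grows. \code{groundTruthSummary} returns the population
#' \linkS4class{ManifoldSummary} of one concept.
#'
#' @param spec a \linkS4class{ManifoldSpec}.
#' @param conceptA,conceptB ordered concept pair.
#' @param concept single concept for \code{groundTruthSummary}.
#' @param m shot count.
#' @return a \linkS4class{PairGeometry} /
#'   \linkS4class{ManifoldSummary}.
#' @export
groundTruthGeometry <- function(spec, conceptA, conceptB, m) {
    pairGeometry(.summaryFromSpec(spec, conceptA),
                 .summaryFromSpec(spec, conceptB), m)
}

#' @rdname groundTruthGeometry
#' @export
groundTruthSummary <- function(spec, concept) {
    .summaryFromSpec(spec, concept)
}

#' Add trial-to-trial measurement noise
#'
#' Replicates every exemplar \code{nTrials} times and adds zero-mean
#' Gaussian measurement noise whose average per-unit variance equals
#' (signal variance) / \code{measurementSnr}, where the signal variance
#' is the per-unit variance of the noiseless activity across exemplars,
#' averaged over units. This is the measurement-SNR convention
#' \eqn{SNR_m =} variance of average activity across images / average
#' noise variance. Uncorrelated noise is independent per unit;
#' correlated noise draws a random full covariance (Wishart with V
#' degrees of freedom, rescaled so its mean diagonal matches the target
#' noise variance). The signal is fixed per exemplar; noise is fresh per
#' trial. Trial identifiers group the replicates of each exemplar.
#'
#' @param x an \linkS4class{ActivitySet} of noiseless exemplars (no
#'   trial column).
#' @param measurementSnr positive measurement SNR.
#' @param correlated logical; correlated or independent unit noise.
#' @param nTrials replicates per exemplar.
#' @param seed RNG seed.
#' @return trial-level \linkS4class{ActivitySet}.
#' @export
addMeasurementNoise <- function(x, measurementSnr, correlated = FALSE,
                                nTrials = 1L, seed) {
    if (!is.numeric(measurementSnr) || measurementSnr <= 0)
        stop("'measurementSnr' must be positive")
    nTrials <- .assertCount(nTrials, "nTrials")
    pat <- activityPatterns(x)
    V <- ncol(pat)
    sigVar <- mean(apply(pat, 2L, var))
    noiseVar <- sigVar / measurementSnr
    n <- nrow(pat) * nTrials
    withSeed(seed, {
        noise <- if (correlated) {
            A <- matrix(rnorm(V * V), V, V)
            Sigma <- tcrossprod(A) / V
            Sigma <- Sigma * (noiseVar / mean(diag(Sigma)))
            matrix(rnorm(n * V), n, V) %*% chol(Sigma)
        } else {
            matrix(rnorm(n * V, sd = sqrt(noiseVar)), n, V)
        }
        rep_ix <- rep(seq_len(nrow(pat)), each = nTrials)
        ActivitySet(pat[rep_ix, , drop = FALSE] + noise,
                    conceptLabels(x)[rep_ix], trials = rep_ix)
    })
}

#' Average trials per exemplar
#'
#' Collapses trial replicates to one row per exemplar by averaging
#' \code{nSamples} of each exemplar's trials (all trials by default),
#' reducing the effective measurement-noise variance by the factor
#' \code{nSamples}. When fewer than all trials are averaged, the subset
#' is drawn without replacement under the seed.
#'
#' @param x an \linkS4class{ActivitySet} with trial identifiers.
#' @param nSamples trials to average per exemplar (default: all).
#' @param seed RNG seed, required when subsampling trials.
#' @return an \linkS4class{ActivitySet} with one row per exemplar and no
#'   trial column.
#' @export
trialAverage <- function(x, nSamples = NULL, seed = NULL) {
    tr <- trialIds(x)
    if (is.null(tr))
        stop("trial identifiers are required for trial averaging")
    pat <- activityPatterns(x)
    lab <- conceptLabels(x)
    groups <- split(seq_along(tr), tr)
    sizes <- lengths(groups)
    if (!is.null(nSamples)) {
        nSamples <- .assertCount(nSamples, "nSamples")
        if (any(sizes < nSamples))
            stop("some exemplars have fewer than ", nSamples, " trials")
    }
    pick <- withSeed(seed, lapply(groups, function(g) {
        if (is.null(nSamples) || length(g) == nSamples) g
        else {
            if (is.null(seed))
                stop("a seed is required to subsample trials")
            sample(g, nSamples)
        }
    }))
    avg <- t(vapply(pick, function(g)
        colMeans(pat[g, , drop = FALSE]), numeric(ncol(pat))))
    ActivitySet(avg, vapply(groups, function(g) lab[g[1]], character(1)))
}

#' Measurement-noise distortion experiment
#'
#' Quantifies how trial-to-trial measurement noise distorts geometry
#' estimates: over a grid of measurement SNR values, noise correlation
#' modes and trial-averaging depths, samples noiseless manifolds from
#' the spec, corrupts them, averages trials, re-estimates the pairwise
#' geometry and tabulates the across-pair mean of each property next to
#' its analytic ground-truth (asymptotic) value. Noise inflates
#' Dimensionality while deflating geometric SNR and Signal; deeper trial
#' averaging moves every estimate toward its asymptote.
#'
#' @param spec a \linkS4class{ManifoldSpec}.
#' @param snrGrid positive measurement-SNR values.
#' @param nSamplesList trial-averaging depths, e.g. \code{c(1, 3, 5)}.
#' @param m shot count.
#' @param seed master seed.
#' @param correlatedModes logical vector of noise modes to run.
#' @param nReps independent replications of the whole experiment.
#' @return data.frame with one row per (replicate, measurement SNR,
#'   noise mode, averaging depth): estimated \code{snr, signal,
#'   dimensionality, combined_overlap, overlap_a, overlap_b, overlap_ab}
#'   (means across ordered pairs) and matching \code{true_*} columns.
#' @export
noiseDistortionExperiment <- function(spec, snrGrid, nSamplesList, m,
                                      seed,
                                      correlatedModes = c(FALSE, TRUE),
                                      nReps = 1L) {
    if (length(snrGrid) < 1L || any(snrGrid <= 0))
        stop("'snrGrid' must be positive")
    nSamplesList <- sort(unique(as.integer(nSamplesList)))
    nReps <- .assertCount(nReps, "nReps")
    cn <- spec@conceptNames
    pairs <- expand.grid(b = cn, a = cn, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    truth <- lapply(seq_len(nrow(pairs)), function(i)
        groundTruthGeometry(spec, pairs$a[i], pairs$b[i], m))
    trueMeans <- c(
        true_snr = mean(vapply(truth, geometricSNR, numeric(1))),
        true_signal = mean(vapply(truth, geometricSignal, numeric(1))),
        true_dimensionality =
            mean(vapply(truth, dimensionality, numeric(1))),
        true_combined_overlap =
            mean(vapply(truth, combinedOverlap, numeric(1))))
    nTrials <- max(nSamplesList)
    seeds <- spawnSeeds(seed,
        nReps * (1L + length(correlatedModes) * length(snrGrid) *
                     (1L + length(nSamplesList))))
    si <- 0L
    nextSeed <- function() {
        si <<- si + 1L
        seeds[si]
    }
    out <- list()
    for (rep in seq_len(nReps)) {
        clean <- sampleManifolds(spec, seed = nextSeed())
        for (corr in correlatedModes) for (snrM in snrGrid) {
            noisy <- addMeasurementNoise(clean, snrM, corr, nTrials,
                                         seed = nextSeed())
            for (nS in nSamplesList) {
                avg <- trialAverage(noisy, nS, seed = nextSeed())
                gg <- geometryGrid(avg, m)$pairs
                out[[length(out) + 1L]] <- data.frame(
                    rep = rep, measurement_snr = snrM,
                    correlated = corr, n_samples = nS,
                    snr = mean(gg$snr), signal = mean(gg$signal),
                    dimensionality = mean(gg$dimensionality_a),
                    combined_overlap = mean(gg$combined_overlap),
                    overlap_a = mean(gg$overlap_a),
                    overlap_b = mean(gg$overlap_b),
                    overlap_ab = mean(gg$overlap_ab),
                    t(trueMeans))
            }
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
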