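#' Estimate the geometry of a single concept manifold
#'
#' Computes the centroid of the exemplar cloud and a principal component
#' analysis of the centered patterns. With \code{X} the P-by-V matrix of
#' one concept's exemplars, the radii are the standard deviations along
#' the principal directions, \eqn{r_i^2 = a_i}, where \eqn{a_i} are the
#' eigenvalues of the covariance \eqn{X_c' X_c / P} (equivalently
#' \eqn{a_i P} is the i-th squared singular value of the centered data).
#' All \eqn{\min(P-1, V)} components are retained; no variance threshold
#' is applied. The squared total radius is \eqn{R^2 = \sum_i r_i^2} and
#' the Dimensionality is the participation ratio
#' \eqn{D = R^4 / \sum_i r_i^4}.
#'
#' @param x a P-by-V matrix of one concept's exemplar patterns (rows are
#'   exemplars), or an \linkS4class{ActivitySet}.
#' @param concept for the \code{ActivitySet} method, which concept to
#'   summarize.
#' @param ... passed between methods.
#' @return a \linkS4class{ManifoldSummary}.
#' @details A manifold with zero total variance (all exemplars identical)
#'   is degenerate and raises an error, as does input with fewer than two
#'   exemplars.
#' @examples
#' X <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
#' dimensionality(estimateManifold(X))   # 2: isotropic in the plane
#' @rdname estimateManifold
#' @export
setMethod("estimateManifold", "matrix", function(x, concept = "concept",
                                                 ...) {
    x <- .assertPatternMatrix(x)
    P <- nrow(x)
    if (P < 2L)
        stop("at least 2 exemplars are required to estimate a manifold")
    ctr <- colMeans(x)
    xc <- sweep(x, 2L, ctr)
    sv <- svd(xc, nu = 0L)
    k <- min(P - 1L, ncol(x))
    radii <- sv$d[seq_len(k)] / sqrt(P)
    if (sum(radii^2) <= 0 || max(radii) < .Machine$double.eps * max(1, max(abs(x))))
        stop("degenerate manifold: zero total variance ",
             "(all exemplars identical)")
    r2 <- radii^2
    new("ManifoldSummary",
        concept = as.character(concept),
        centroid = ctr,
        radii = radii,
        directions = sv$v[, seq_len(k), drop = FALSE],
        totalRadiusSq = sum(r2),
        dimensionality = sum(r2)^2 / sum(r2^2),
        nExemplars = P)
})

#' @rdname estimateManifold
#' @export
setMethod("estimateManifold", "ActivitySet", function(x, concept, ...) {
    estimateManifold(.conceptMatrix(x, concept), concept = concept)
})

#' ManifoldSummary accessors
#'
#' @param x a \linkS4class{ManifoldSummary}.
#' @return \code{centroid}: length-V numeric; \code{manifoldRadii}:
#'   nonincreasing radii; \code{principalDirections}: V-by-k orthonormal
#'   matrix; \code{totalRadiusSq}, \code{dimensionality},
#'   \code{nExemplars}: scalars.
#' @name ManifoldSummary-accessors
NULL

#' @rdname ManifoldSummary-accessors
#' @export
setMethod("centroid", "ManifoldSummary", function(x) x@centroid)

#' @rdname ManifoldSummary-accessors
#' @export
setMethod("manifoldRadii", "ManifoldSummary", function(x) x@radii)

#' @rdname ManifoldSummary-accessors
#' @export
setMethod("principalDirections", "ManifoldSummary", function(x)
    x@directions)

#' @rdname ManifoldSummary-accessors
#' @export
setMethod("totalRadiusSq", "ManifoldSummary", function(x) x@totalRadiusSq)

#' @rdname ManifoldSummary-accessors
#' @export
setMethod("dimensionality", "ManifoldSummary", function(x)
    x@dimensionality)

#' @rdname ManifoldSummary-accessors
#' @export
setMethod("nExemplars", "ManifoldSummary", function(x) x@nExemplars)

setMethod("show", "ManifoldSummary", function(object) {
    cat("ManifoldSummary for concept '", object@concept, "'\n", sep = "")
    cat(sprintf("  ambient dim %d, %d components, %d exemplars\n",
                length(object@centroid), length(object@radii),
                object@nExemplars))
    cat(sprintf("  R^2 = %.4g, Dimensionality = %.3f\n",
                object@totalRadiusSq, object@dimensionality))
})

#' Pairwise manifold geometry of the few-shot theory
#'
#' For an ordered concept pair (a, b), computes the geometric Signal
#' \eqn{S_{a,b} = \|\Delta x\|^2} with
#' \eqn{\Delta x = (x_0^a - x_0^b)/R_a}, the Bias
#' \eqn{b_{a,b} = R_b^2/R_a^2 - 1}, the Noise-Signal Overlaps
#' \eqn{N^a = \|\Delta x \cdot U^a\|^2}, \eqn{N^b = \|\Delta x \cdot U^b\|^2}
#' and the Noise-Noise Overlap \eqn{N^{ab} = \|(U^a)' U^b\|_F^2}, where
#' \eqn{U^a, U^b} are the radius-weighted direction matrices with columns
#' \eqn{r_i u_i / R_a} (both normalized by the reference manifold's
#' radius \eqn{R_a}). The geometric SNR retains only the terms linear in
#' \eqn{1/m}:
#' \deqn{SNR_{a,b}(m) = \frac{\frac{1}{2}(S_{a,b} + b_{a,b}/m)}
#'   {\sqrt{(D_a^{-1} + N^b_{a,b} + N^{ab}_{a,b})/m + N^a_{a,b}}}}
#' and the predicted m-shot error is \eqn{H(SNR(m))}
#' (\code{\link{gaussianTailError}}). All quantities describe concept a
#' relative to concept b, so the pair is ordered:
#' \code{pairGeometry(a, b, m)} and \code{pairGeometry(b, a, m)} differ
#' in general.
#'
#' @param a,b \linkS4class{ManifoldSummary} objects sharing the ambient
#'   dimension; \code{a} is the reference concept.
#' @param m shot count (positive integer).
#' @param ... unused.
#' @return a \linkS4class{PairGeometry}.
#' @examples
#' spec <- manifoldSpec(ambientDim = 20,
#'                      centers = cbind(a = rep(0, 20), b = rep(0.4, 20)),
#'                      spectra = list(rep(1, 5), rep(1, 5)), seed = 7)
#' ds <- sampleManifolds(spec, 600, seed = 1)
#' A <- estimateManifold(ds, "a"); B <- estimateManifold(ds, "b")
#' geometricSNR(pairGeometry(A, B, m = 5))
#' @rdname pairGeometry
#' @export
setMethod("pairGeometry", signature("ManifoldSummary", "ManifoldSummary"),
    function(a, b, m, ...) {
    m <- .assertCount(m, "m")
    if (length(a@centroid) != length(b@centroid))
        stop("manifolds live in different ambient dimensions")
    Ra2 <- a@totalRadiusSq
    Rb2 <- b@totalRadiusSq
    if (Ra2 <= 0)
        stop("degenerate reference manifold: zero total radius")
    dx <- (a@centroid - b@centroid) / sqrt(Ra2)
    # radius-weighted, Ra-normalized direction matrices
    Ua <- sweep(a@directions, 2L, a@radii, `*`) / sqrt(Ra2)
    Ub <- sweep(b@directions, 2L, b@radii, `*`) / sqrt(Ra2)
    S  <- sum(dx^2)
    bb <- Rb2 / Ra2 - 1
    Na  <- sum(drop(crossprod(Ua, dx))^2)
    Nb  <- sum(drop(crossprod(Ub, dx))^2)
    Nab <- sum(crossprod(Ua, Ub)^2)
    Da <- a@dimensionality
    snr <- 0.5 * (S + bb / m) / sqrt((1 / Da + Nb + Nab) / m + Na)
    new("PairGeometry",
        conceptA = a@concept, conceptB = b@concept, m = m,
        signal = S, bias = bb,
        overlapA = Na, overlapB = Nb, overlapAB = Nab,
        combinedOverlap = (Nb + Nab) / m + Na,
        snr = snr,
        predictedError = gaussianTailError(snr),
        dimensionalityA = Da)
})

#' PairGeometry accessors
#'
#' @param x a \linkS4class{PairGeometry}.
#' @return scalars; \code{overlaps} returns the named vector
#'   \code{c(a = N^a, b = N^b, ab = N^ab)}.
#' @name PairGeometry-accessors
NULL

#' @rdname PairGeometry-accessors
#' @export
setMethod("geometricSignal", "PairGeometry", function(x) x@signal)

#' @rdname PairGeometry-accessors
#' @export
setMethod("geometricBias", "PairGeometry", function(x) x@bias)

#' @rdname PairGeometry-accessors
#' @export
setMethod("overlaps", "PairGeometry", function(x)
    c(a = x@overlapA, b = x@overlapB, ab = x@overlapAB))

#' @rdname PairGeometry-accessors
#' @export
setMethod("combinedOverlap", "PairGeometry", function(x)
    x@combinedOverlap)

#' @rdname PairGeometry-accessors
#' @export
setMethod("geometricSNR", "PairGeometry", function(x) x@snr)

#' @rdname PairGeometry-accessors
#' @export
setMethod("predictedError", "PairGeometry", function(x) x@predictedError)

#' @rdname PairGeometry-accessors
#' @export
setMethod("dimensionality", "PairGeometry", function(x)
    x@dimensionalityA)

setMethod("show", "PairGeometry", function(object) {
    cat(sprintf("PairGeometry ('%s' relative to '%s'), m = %d\n",
                object@conceptA, object@conceptB, object@m))
    cat(sprintf("  S = %.4g  b = %.4g  D_a = %.3f\n",
                object@signal, object@bias, object@dimensionalityA))
    cat(sprintf("  N^a = %.4g  N^b = %.4g  N^ab = %.4g  N(m) = %.4g\n",
                object@overlapA, object@overlapB, object@overlapAB,
                object@combinedOverlap))
    cat(sprintf("  SNR(m) = %.4f  predicted error = %.4f\n",
                object@snr, object@predictedError))
})

#' Gaussian tail function mapping SNR to predicted error
#'
#' \eqn{H(z) = \frac{1}{2}(1 - erf(z/\sqrt{2}))}, the upper-tail
#' probability of the standard normal distribution: the error rate of an
#' m-shot prototype classifier with geometric SNR(m) equal to \code{z}.
#' Strictly decreasing, with \eqn{H(0) = 1/2} and
#' \eqn{H(z) + H(-z) = 1}.
#'
#' @param snr finite numeric (vectorized).
#' @return predicted error in (0, 1).
#' @examples
#' gaussianTailError(0)    # 0.5
#' gaussianTailError(1)    # upper-tail probability at 1
#' @export
gaussianTailError <- function(snr) {
    if (!is.numeric(snr) || any(!is.finite(snr)))
        stop("'snr' must be finite numeric")
    pnorm(snr, lower.tail = FALSE)
}

#' All pairwise geometric quantities of a labeled dataset
#'
#' Estimates a \linkS4class{ManifoldSummary} for every concept and a
#' \linkS4class{PairGeometry} for every ordered pair of distinct
#' concepts. Concepts with fewer than two exemplars or zero total
#' variance are excluded with a warning.
#'
#' @param x an \linkS4class{ActivitySet} with at least two concepts.
#' @param m shot count used for the SNR(m) and combined Overlap.
#' @param ... unused.
#' @return a list with elements \code{pairs} (data.frame, one row per
#'   ordered pair: \code{concept_a, concept_b, m, signal, bias,
#'   overlap_a, overlap_b, overlap_ab, combined_overlap, snr,
#'   predicted_error, dimensionality_a}), \code{concepts} (data.frame
#'   with per-concept \code{dimensionality, total_radius_sq,
#'   n_exemplars}) and \code{manifolds} (named list of
#'   \linkS4class{ManifoldSummary}).
#' @rdname geometryGrid
#' @export
setMethod("geometryGrid", "ActivitySet", function(x, m, ...) {
    m <- .assertCount(m, "m")
    idx <- .conceptIndex(x)
    if (length(idx) < 2L)
        stop("at least 2 concepts are required for pairwise geometry")
    pat <- activityPatterns(x)
    manifolds <- list()
    for (cc in names(idx)) {
        if (length(idx[[cc]]) < 2L) {
            warning("concept '", cc, "' has fewer than 2 exemplars; excluded")
            next
        }
        ms <- tryCatch(
            estimateManifold(pat[idx[[cc]], , drop = FALSE], concept = cc),
            error = function(e) {
                warning("concept '", cc, "' excluded: ",
                        conditionMessage(e))
                NULL
            })
        if (!is.null(ms)) manifolds[[cc]] <- ms
    }
    if (length(manifolds) < 2L)
        stop("fewer than 2 non-degenerate concepts remain")
    cn <- names(manifolds)
    pairs <- expand.grid(concept_b = cn, concept_a = cn,
                         stringsAsFactors = FALSE)[, 2:1]
    pairs <- pairs[pairs$concept_a != pairs$concept_b, , drop = FALSE]
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
        pg <- pairGeometry(manifolds[[pairs$concept_a[i]]],
                           manifolds[[pairs$concept_b[i]]], m)
        data.frame(concept_a = pg@conceptA, concept_b = pg@conceptB,
                   m = pg@m, signal = pg@signal, bias = pg@bias,
                   overlap_a = pg@overlapA, overlap_b = pg@overlapB,
                   overlap_ab = pg@overlapAB,
                   combined_overlap = pg@combinedOverlap,
                   snr = pg@snr, predicted_error = pg@predictedError,
                   dimensionality_a = pg@dimensionalityA)
    })
    concepts <- data.frame(
        concept = cn,
        dimensionality = vapply(manifolds, dimensionality, numeric(1)),
        total_radius_sq = vapply(manifolds, totalRadiusSq, numeric(1)),
        n_exemplars = vapply(manifolds, nExemplars, integer(1)),
        row.names = NULL)
    list(pairs = do.call(rbind, rows), concepts = concepts,
         manifolds = manifolds)
})

#' Two-dimensional Signal-plane projection of a concept pair
#'
#' Projects the exemplars of two concepts onto the plane spanned by the
#' Signal direction (the unit vector along the centroid difference
#' \eqn{x_0^a - x_0^b}; x-axis) and the direction orthogonal to it with
#' maximum variance in the pooled, centered two-concept data (y-axis).
#' This is the visualization plane in which manifold disentanglement can
#' be inspected by eye.
#'
#' @param x an \linkS4class{ActivitySet}.
#' @param conceptA,conceptB the two concepts to display.
#' @return a list with \code{coords} (data.frame: \code{concept, x, y}
#'   per exemplar), \code{centroids} (data.frame: one row per concept)
#'   and \code{axes} (V-by-2 orthonormal matrix). Coordinates are
#'   relative to the pooled mean.
#' @details Coincident centroids leave the Signal direction undefined and
#'   raise an error.
#' @export
project2D <- function(x, conceptA, conceptB) {
    Xa <- .conceptMatrix(x, conceptA)
    Xb <- .conceptMatrix(x, conceptB)
    ca <- colMeans(Xa)
    cb <- colMeans(Xb)
    d <- ca - cb
    nd <- sqrt(sum(d^2))
    if (nd <= .Machine$double.eps * max(1, max(abs(ca)), max(abs(cb))))
        stop("signal direction undefined: coincident centroids")
    ax <- d / nd
    pooled <- rbind(Xa, Xb)
    pc <- sweep(pooled, 2L, colMeans(pooled))
    resid <- pc - (pc %*% ax) %*% t(ax)
    ay <- svd(resid, nu = 0L, nv = 1L)$v[, 1]
    ay <- ay - sum(ay * ax) * ax     # guard orthogonality numerically
    ay <- ay / sqrt(sum(ay^2))
    axes <- cbind(signal = ax, residual_pc1 = ay)
    co <- pc %*% axes
    concept <- c(rep(conceptA, nrow(Xa)), rep(conceptB, nrow(Xb)))
    ctr <- rbind(ca - colMeans(pooled), cb - colMeans(pooled)) %*% axes
    list(coords = data.frame(concept = concept, x = co[, 1], y = co[, 2]),
         centroids = data.frame(concept = c(conceptA, conceptB),
                                x = ctr[, 1], y = ctr[, 2]),
         axes = axes)
}
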