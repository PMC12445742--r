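#' Build an m-shot prototype
#'
#' The prototype is the mean of \code{m} exemplars sampled without
#' replacement under the seed. With \code{m} equal to the number of
#' available exemplars this is the empirical centroid.
#'
#' @param exemplars matrix of available exemplar patterns (rows).
#' @param m shot count.
#' @param seed RNG seed for the draw (NULL leaves the RNG state alone).
#' @return length-V prototype vector.
#' @export
buildPrototype <- function(exemplars, m, seed = NULL) {
    exemplars <- .assertPatternMatrix(exemplars)
    m <- .assertCount(m, "m")
    if (nrow(exemplars) < m)
        stop("fewer than m = ", m, " exemplars available")
    take <- withSeed(seed, sample.int(nrow(exemplars), m))
    colMeans(exemplars[take, , drop = FALSE])
}

#' Nearest-prototype pairwise classification
#'
#' Assigns every test pattern to the nearer of two prototypes. This is
#' the linear read-out of the few-shot theory: patterns are projected
#' onto the vector connecting the prototypes and thresholded at its
#' midpoint, which is equivalent to the nearest prototype in Euclidean
#' distance. Exact midpoint ties are assigned to the first prototype
#' (deterministic convention; ties have measure zero for continuous
#' data).
#'
#' @param test matrix of test patterns (rows).
#' @param protoA,protoB distinct prototype vectors.
#' @param labels length-2 labels to return, default \code{c("a", "b")}.
#' @return character vector of predicted labels, one per test row.
#' @export
classifyPair <- function(test, protoA, protoB, labels = c("a", "b")) {
    test <- .assertPatternMatrix(test)
    if (isTRUE(all.equal(protoA, protoB, tolerance = 0)) ||
        sum((protoA - protoB)^2) == 0)
        stop("identical prototypes: decision boundary undefined")
    # d^2(x, pA) - d^2(x, pB) = -2 x.(pA - pB) + |pA|^2 - |pB|^2
    w <- protoA - protoB
    dd <- -2 * unname(drop(test %*% w)) + sum(protoA^2) - sum(protoB^2)
    ifelse(dd <= 0, labels[1], labels[2])
}

#' Empirical m-shot error via the nested resampling protocol
#'
#' For each outer fold, exemplars of every concept are split into a
#' larger (~90\%) group on which the pairwise geometry is computed, and a
#' smaller (~10\%) holdout. In each of \code{nInner} inner draws,
#' \code{m} holdout exemplars per concept form the prototype and the
#' remaining holdout exemplars are classified against every other
#' concept's prototype. Errors are averaged over inner draws, then the
#' mean and standard deviation over the \code{nOuter} outer folds are
#' reported. Geometry on the complementary 90\% makes empirical error and
#' geometric SNR paired observations fold by fold.
#'
#' When trial repeats are present they are averaged into one exemplar row
#' before splitting, so folds are leakage-free. The holdout size is
#' \code{floor(holdoutFraction * P)} with a floor of \code{m + 1} rows.
#' A master seed spawns an independent stream per outer fold, so results
#' are reproducible and fold-order independent.
#'
#' @param x an \linkS4class{ActivitySet} with \eqn{\ge 2} concepts.
#' @param m shot count.
#' @param nOuter,nInner outer/inner fold counts (default 16 each).
#' @param holdoutFraction fraction of exemplars held out (default 0.10).
#' @param seed master seed (required).
#' @return a \linkS4class{FewShotResult}; \code{foldGeometry(result)}
#'   holds the per-outer-fold \code{pairGeometry} table.
#' @export
fewShotErrorProtocol <- function(x, m, nOuter = 16L, nInner = 16L,
                                 holdoutFraction = 0.10, seed) {
    m <- .assertCount(m, "m")
    nOuter <- .assertCount(nOuter, "nOuter")
    nInner <- .assertCount(nInner, "nInner")
    if (missing(seed) || is.null(seed))
        stop("a seed is required for the resampling protocol")
    seed <- as.integer(seed)
    if (!is.null(trialIds(x)))
        x <- trialAverage(x)
    idx <- .conceptIndex(x)
    if (length(idx) < 2L)
        stop("at least 2 concepts are required")
    pat <- activityPatterns(x)
    cn <- names(idx)
    nh <- integer(length(cn)); names(nh) <- cn
    for (cc in cn) {
        P <- length(idx[[cc]])
        h <- max(floor(holdoutFraction * P), m + 1L)
        if (P - h < 2L || h <= m)
            stop("concept '", cc, "' has too few exemplars (", P,
                 ") for m = ", m, " with holdout fraction ",
                 holdoutFraction)
        nh[cc] <- h
    }
    C <- length(cn)
    errFold <- array(NA_real_, c(C, C, nOuter),
                     dimnames = list(cn, cn, NULL))
    outerSeeds <- spawnSeeds(seed, nOuter)
    foldGeo <- vector("list", nOuter)
    for (o in seq_len(nOuter)) {
        fold <- withSeed(outerSeeds[o], {
            hold <- train <- list()
            for (cc in cn) {
                perm <- sample(idx[[cc]])
                hold[[cc]] <- perm[seq_len(nh[cc])]
                train[[cc]] <- perm[-seq_len(nh[cc])]
            }
            manifolds <- lapply(cn, function(cc)
                estimateManifold(pat[train[[cc]], , drop = FALSE],
                                 concept = cc))
            names(manifolds) <- cn
            geo <- list()
            err <- matrix(0, C, C, dimnames = list(cn, cn))
            for (a in cn) for (b in cn) if (a != b) {
                pg <- pairGeometry(manifolds[[a]], manifolds[[b]], m)
                geo[[paste(a, b, sep = "\r")]] <- data.frame(
                    fold = o, concept_a = a, concept_b = b, m = m,
                    signal = pg@signal, bias = pg@bias,
                    overlap_a = pg@overlapA, overlap_b = pg@overlapB,
                    overlap_ab = pg@overlapAB,
                    combined_overlap = pg@combinedOverlap,
                    snr = pg@snr, predicted_error = pg@predictedError,
                    dimensionality_a = pg@dimensionalityA)
            }
            for (i in seq_len(nInner)) {
                shot <- lapply(cn, function(cc)
                    sample(hold[[cc]], m))
                names(shot) <- cn
                protos <- lapply(cn, function(cc)
                    colMeans(pat[shot[[cc]], , drop = FALSE]))
                names(protos) <- cn
                for (a in cn) for (b in cn) if (a != b) {
                    testRows <- setdiff(hold[[a]], shot[[a]])
                    pred <- classifyPair(pat[testRows, , drop = FALSE],
                                         protos[[a]], protos[[b]],
                                         labels = c(a, b))
                    err[a, b] <- err[a, b] + mean(pred != a)
                }
            }
            list(err = err / nInner, geo = do.call(rbind, geo))
        })
        errFold[, , o] <- fold$err
        foldGeo[[o]] <- fold$geo
    }
    em <- apply(errFold, c(1, 2), mean)
    es <- apply(errFold, c(1, 2), sd)
    diag(em) <- NA_real_
    diag(es) <- NA_real_
    fg <- do.call(rbind, foldGeo)
    rownames(fg) <- NULL
    new("FewShotResult", errorMean = em, errorStd = es, m = m,
        nOuter = nOuter, nInner = nInner,
        holdoutFraction = holdoutFraction, seed = seed,
        foldGeometry = fg)
}

#' FewShotResult accessors
#'
#' @param x a \linkS4class{FewShotResult}.
#' @return \code{errorMean}/\code{errorStd}: concept-by-concept matrices
#'   (diagonal \code{NA}); \code{foldGeometry}: per-outer-fold pairwise
#'   geometry data.frame.
#' @name FewShotResult-accessors
NULL

#' @rdname FewShotResult-accessors
#' @export
setMethod("errorMean", "FewShotResult", function(x) x@errorMean)

#' @rdname FewShotResult-accessors
#' @export
setMethod("errorStd", "FewShotResult", function(x) x@errorStd)

#' @rdname FewShotResult-accessors
#' @export
setMethod("foldGeometry", "FewShotResult", function(x) x@foldGeometry)

setMethod("show", "FewShotResult", function(object) {
    cat(sprintf("FewShotResult: %d-shot, %d concepts, %dx%d folds, seed %d\n",
                object@m, nrow(object@errorMean), object@nOuter,
                object@nInner, object@seed))
    cat(sprintf("  mean off-diagonal error = %.4f\n",
                mean(object@errorMean, na.rm = TRUE)))
})

#' Symmetry of an error (or accuracy) matrix
#'
#' Pearson correlation between the vectorized strict upper triangle and
#' the transpose-matched strict lower triangle: 1 for an exactly
#' symmetric matrix, -1 for a perfectly reversed one.
#'
#' @param errorMatrix square matrix over at least 3 concepts.
#' @return correlation in [-1, 1].
#' @export
symmetryScore <- function(errorMatrix) {
    errorMatrix <- as.matrix(errorMatrix)
    if (nrow(errorMatrix) != ncol(errorMatrix) || nrow(errorMatrix) < 3L)
        stop("a square matrix over >= 3 concepts is required")
    up <- errorMatrix[upper.tri(errorMatrix)]
    lo <- t(errorMatrix)[upper.tri(errorMatrix)]
    keep <- is.finite(up) & is.finite(lo)
    up <- up[keep]; lo <- lo[keep]
    if (length(up) < 2L || sd(up) == 0 || sd(lo) == 0)
        stop("constant triangles: symmetry correlation undefined")
    cor(up, lo)
}

#' Classification success as a function of concept-hierarchy distance
#'
#' Relates empirical few-shot success (1 - error) to hop distances on a
#' concept hierarchy: per-integer-distance bin means and the overall
#' Pearson correlation between success and distance across all ordered
#' pairs.
#'
#' @param result a \linkS4class{FewShotResult}, or an error matrix with
#'   concept dimnames.
#' @param distances symmetric matrix of nonnegative integer hop counts
#'   over the same concept set (see
#'   \code{\link{hierarchyPathDistance}}).
#' @return a list with \code{curve} (data.frame: \code{distance,
#'   mean_success, mean_error, n_pairs}) and \code{correlation} (Pearson
#'   r between success and distance; \code{NA} with a warning if all
#'   distances coincide).
#' @export
accuracyVsDistance <- function(result, distances) {
    em <- if (is(result, "FewShotResult")) errorMean(result) else
        as.matrix(result)
    cn <- rownames(em)
    if (is.null(cn) || !setequal(cn, rownames(distances)))
        stop("concept sets of the error and distance matrices differ")
    distances <- distances[cn, cn]
    off <- row(em) != col(em)
    ok <- off & is.finite(em) & is.finite(distances)
    err <- em[ok]
    d <- distances[ok]
    succ <- 1 - err
    curve <- aggregate(data.frame(mean_success = succ, mean_error = err),
                       by = list(distance = d), FUN = mean)
    curve$n_pairs <- as.integer(table(factor(d, levels = curve$distance)))
    if (length(unique(d)) < 2L) {
        warning("all pairs share one hierarchy distance; ",
                "correlation undefined")
        r <- NA_real_
    } else {
        r <- cor(succ, d)
    }
    list(curve = curve, correlation = r)
}
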