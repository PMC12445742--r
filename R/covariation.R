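#' Log-linear model of the combined Overlap
#'
#' Fits \eqn{\log N(m) = \alpha \log S + \beta \log D + \gamma} by
#' ordinary least squares on natural-log-transformed variables across
#' concept pairs, where \eqn{N(m)} is the combined Overlap, \eqn{S} the
#' geometric Signal and \eqn{D} the Dimensionality of the reference
#' concept. Pairs with nonpositive \eqn{S}, \eqn{D} or \eqn{N(m)} are
#' excluded with a warning (the logarithm is undefined there). The
#' single-predictor (log S only) R-squared is reported for comparison.
#'
#' @param pairs data.frame with columns \code{signal},
#'   \code{dimensionality_a} and \code{combined_overlap} (e.g. the
#'   \code{pairs} element of \code{\link{geometryGrid}}, or
#'   \code{\link{foldGeometry}} rows).
#' @param m shot count the Overlap was computed at (default: taken from
#'   the \code{m} column).
#' @return a \linkS4class{LogLinearFit}.
#' @export
fitLogLinearOverlap <- function(pairs, m = NULL) {
    need <- c("signal", "dimensionality_a", "combined_overlap")
    if (!all(need %in% colnames(pairs)))
        stop("'pairs' must contain columns ",
             paste(need, collapse = ", "))
    if (is.null(m)) {
        if (!("m" %in% colnames(pairs)))
            stop("'m' not given and no m column present")
        m <- unique(pairs$m)
        if (length(m) != 1L)
            stop("'pairs' mixes several shot counts; pass 'm' explicitly")
    }
    m <- .assertCount(m, "m")
    S <- pairs$signal
    D <- pairs$dimensionality_a
    N <- pairs$combined_overlap
    ok <- is.finite(S) & is.finite(D) & is.finite(N) &
        S > 0 & D > 0 & N > 0
    if (sum(!ok) > 0)
        warning(sum(!ok), " pair(s) with nonpositive S, D or N(m) ",
                "excluded from the log-linear fit")
    if (sum(ok) < 3L)
        stop("at least 3 pairs with positive S, D, N(m) are required")
    df <- data.frame(lN = log(N[ok]), lS = log(S[ok]), lD = log(D[ok]))
    fit <- lm(lN ~ lS + lD, data = df)
    if (any(is.na(coef(fit))))
        stop("rank-deficient design: log S and log D do not span ",
             "two dimensions")
    sm <- summary(fit)
    r2s <- summary(lm(lN ~ lS, data = df))$r.squared
    cf <- coef(fit)
    se <- sm$coefficients[, "Std. Error"]
    new("LogLinearFit",
        alpha = unname(cf["lS"]), beta = unname(cf["lD"]),
        gamma = unname(cf["(Intercept)"]),
        coefSe = c(gamma = unname(se["(Intercept)"]),
                   alpha = unname(se["lS"]), beta = unname(se["lD"])),
        rSquared = sm$r.squared, rSquaredSignalOnly = r2s,
        m = m, nPoints = as.integer(sum(ok)),
        nExcluded = as.integer(sum(!ok)))
}

setMethod("show", "LogLinearFit", function(object) {
    cat(sprintf("LogLinearFit (m = %d): log N = %.4f log S + %.4f log D + %.4f\n",
                object@m, object@alpha, object@beta, object@gamma))
    cat(sprintf("  R^2 = %.4f (log S only: %.4f), n = %d (%d excluded)\n",
                object@rSquared, object@rSquaredSignalOnly,
                object@nPoints, object@nExcluded))
})

#' SNR as a function of Signal and Dimensionality
#'
#' With the combined Overlap replaced by its fitted log-linear model
#' \eqn{\hat N(m) = e^{\gamma} S^{\alpha} D^{\beta}} and the Bias held
#' constant (it is essentially independent of the other properties), the
#' geometric SNR becomes a function of Signal and Dimensionality alone:
#' \deqn{SNR(S, D) = \frac{\frac{1}{2}(S + b/m)}
#'   {\sqrt{(Dm)^{-1} + e^{\gamma} S^{\alpha} D^{\beta}}}}
#' Evaluated over a (S, D) grid; the returned contour levels trace
#' iso-SNR lines, which are slightly curved in log-log coordinates.
#'
#' @param fit a \linkS4class{LogLinearFit}.
#' @param bias constant Bias value (e.g. the per-dataset mean).
#' @param m shot count (default: the fit's).
#' @param sGrid,dGrid strictly positive grid values.
#' @param nLevels number of iso-SNR contour levels to return.
#' @return a list with \code{surface} (length(sGrid)-by-length(dGrid)
#'   matrix of SNR values), \code{grid} (long data.frame \code{S, D,
#'   snr}) and \code{levels} (iso-SNR contour levels).
#' @export
snrSurface <- function(fit, bias, m = NULL, sGrid, dGrid, nLevels = 10L) {
    stopifnot(is(fit, "LogLinearFit"))
    if (is.null(m)) m <- fit@m
    m <- .assertCount(m, "m")
    if (any(sGrid <= 0) || any(dGrid <= 0))
        stop("grid values must be strictly positive")
    f <- function(S, D) {
        Nhat <- exp(fit@gamma) * S^fit@alpha * D^fit@beta
        0.5 * (S + bias / m) / sqrt(1 / (D * m) + Nhat)
    }
    surface <- outer(sGrid, dGrid, f)
    dimnames(surface) <- list(S = signif(sGrid, 6), D = signif(dGrid, 6))
    grid <- expand.grid(S = sGrid, D = dGrid)
    grid$snr <- as.vector(surface)
    list(surface = surface, grid = grid,
         levels = pretty(range(surface), n = nLevels))
}

#' Pearson correlation with a two-sided permutation test
#'
#' Observed Pearson correlation between \code{x} and \code{y}, with
#' significance from \code{nPermutations} random permutations of
#' \code{y}. The two-sided p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\}) / (n_{perm} + 1)}, so it
#' is never zero.
#'
#' @param x,y numeric vectors of equal length (\eqn{\ge 3}), each with
#'   nonzero variance.
#' @param nPermutations permutations to draw (default 1000).
#' @param seed RNG seed.
#' @return a \linkS4class{PermutationCorrelation}.
#' @export
pearsonPermutation <- function(x, y, nPermutations = 1000L, seed = NULL) {
    if (length(x) != length(y) || length(x) < 3L)
        stop("'x' and 'y' must have equal length >= 3")
    if (sd(x) == 0 || sd(y) == 0)
        stop("constant input: correlation undefined")
    nPermutations <- .assertCount(nPermutations, "nPermutations")
    robs <- cor(x, y)
    # r is linear in the permuted y once x is standardized
    n <- length(x)
    xs <- (x - mean(x)) / (sd(x) * (n - 1))
    ys <- (y - mean(y)) / sd(y)
    rperm <- withSeed(seed, {
        P <- vapply(seq_len(nPermutations),
                    function(i) sample.int(n), integer(n))
        drop(crossprod(xs, matrix(ys[P], n)))
    })
    p <- (1 + sum(abs(rperm) >= abs(robs))) / (nPermutations + 1)
    new("PermutationCorrelation", rho = robs, pValue = p,
        nPermutations = nPermutations)
}

setMethod("show", "PermutationCorrelation", function(object) {
    cat(sprintf("Pearson r = %.4f, permutation p = %.4g (%d permutations)\n",
                object@rho, object@pValue, object@nPermutations))
})

#' Correlation structure of the geometric properties
#'
#' Pairwise Pearson correlations, with permutation p-values, among
#' \{SNR, Signal, Bias, combined Overlap, Dimensionality\} — either
#' across levels (ROIs / network layers) after averaging within level,
#' or across individual concept pairs pooled over levels. An optional
#' fractional-depth window restricts the analysis to a subset of levels
#' (e.g. early layers).
#'
#' @param geometry data.frame with a \code{level} column and columns
#'   \code{snr, signal, bias, combined_overlap, dimensionality_a} (as
#'   produced by \code{\link{geometryGrid}}, with \code{level} added by
#'   the caller); optionally \code{level_fraction} for depth filtering.
#' @param grouping \code{"perLevelAverage"} (default; requires \eqn{\ge
#'   3} levels) or \code{"perPair"}.
#' @param nPermutations,seed passed to
#'   \code{\link{pearsonPermutation}}.
#' @param levelFractionRange optional length-2 numeric; keep levels with
#'   \code{level_fraction} inside the closed interval.
#' @return a list with \code{correlation} and \code{pValue} (symmetric
#'   5-by-5 matrices, unit diagonal / \code{NA} p on the diagonal) and
#'   \code{n} (observations used).
#' @export
propertyCorrelationSuite <- function(geometry,
                                     grouping = c("perLevelAverage",
                                                  "perPair"),
                                     nPermutations = 1000L, seed = NULL,
                                     levelFractionRange = NULL) {
    grouping <- match.arg(grouping)
    props <- c(snr = "snr", signal = "signal", bias = "bias",
               overlap = "combined_overlap",
               dimensionality = "dimensionality_a")
    if (!("level" %in% colnames(geometry)))
        stop("'geometry' must contain a 'level' column")
    if (!all(props %in% colnames(geometry)))
        stop("'geometry' must contain columns ",
             paste(props, collapse = ", "))
    if (!is.null(levelFractionRange)) {
        if (!("level_fraction" %in% colnames(geometry)))
            stop("'level_fraction' column required for depth filtering")
        keep <- geometry$level_fraction >= levelFractionRange[1] &
            geometry$level_fraction <= levelFractionRange[2]
        geometry <- geometry[keep, , drop = FALSE]
    }
    if (grouping == "perLevelAverage") {
        if (length(unique(geometry$level)) < 3L)
            stop("at least 3 levels are required for averaged mode")
        dat <- aggregate(geometry[, props],
                         by = list(level = geometry$level), FUN = mean)
        dat <- dat[, props]
    } else {
        dat <- geometry[, props]
    }
    names(dat) <- names(props)
    k <- length(props)
    seeds <- matrix(NA_integer_, k, k)
    if (!is.null(seed))
        seeds[upper.tri(seeds)] <- spawnSeeds(seed, k * (k - 1) / 2)
    rho <- diag(1, k)
    pv <- matrix(NA_real_, k, k)
    dimnames(rho) <- dimnames(pv) <- list(names(props), names(props))
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
        pc <- tryCatch(
            pearsonPermutation(dat[[i]], dat[[j]], nPermutations,
                               seed = seeds[i, j]),
            error = function(e) NULL)
        if (is.null(pc)) {
            # constant property across observations: undefined
            warning("correlation of '", names(props)[i], "' with '",
                    names(props)[j], "' undefined (constant input)")
            rho[i, j] <- rho[j, i] <- NA_real_
        } else {
            rho[i, j] <- rho[j, i] <- pc@rho
            pv[i, j] <- pv[j, i] <- pc@pValue
        }
    }
    list(correlation = rho, pValue = pv, n = nrow(dat))
}

#' Hop distances on a concept hierarchy
#'
#' Shortest-path hop counts between concepts on an undirected hierarchy
#' graph given as an edge list (e.g. parent-child relations). Pairs in
#' different components get \code{Inf} with a warning.
#'
#' @param edges two-column data.frame (or matrix) of edges, or a path to
#'   a two-column whitespace/tab-delimited edge-list file.
#' @param concepts concepts to include (default: all vertices).
#' @return symmetric matrix of integer hop counts (zero diagonal).
#' @export
hierarchyPathDistance <- function(edges, concepts = NULL) {
    if (is.character(edges) && length(edges) == 1L)
        edges <- utils::read.table(edges, header = FALSE,
                                   col.names = c("parent", "child"),
                                   colClasses = "character")
    edges <- as.data.frame(edges)[, 1:2]
    edges[] <- lapply(edges, as.character)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    verts <- igraph::V(g)$name
    if (is.null(concepts)) concepts <- verts
    missing <- setdiff(concepts, verts)
    if (length(missing))
        stop("concepts absent from the hierarchy: ",
             paste(missing, collapse = ", "))
    d <- igraph::distances(g, v = concepts, to = concepts)
    if (any(!is.finite(d)))
        warning("some concept pairs are disconnected ",
                "(infinite distance)")
    d
}
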