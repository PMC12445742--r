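#' Random subspace: sample units without replacement
#'
#' Restricts a dataset to \code{k} distinct units sampled uniformly
#' without replacement, the first stage of the embedding used to make
#' geometry estimation tractable for very wide layers. When \code{k} is
#' at least the ambient dimension the dataset is returned unchanged (all
#' units, original order), with a warning if \code{k} exceeds it.
#'
#' @param x matrix (exemplar-by-unit) or \linkS4class{ActivitySet}.
#' @param k number of units to retain.
#' @param seed RNG seed of the draw.
#' @param ... unused.
#' @return object of the same class as \code{x}, restricted to the
#'   sampled units (kept in original column order).
#' @rdname randomSubspace
#' @export
setMethod("randomSubspace", "matrix", function(x, k, seed, ...) {
    k <- .assertCount(k, "k")
    V <- ncol(x)
    if (k >= V) {
        if (k > V)
            warning("k = ", k, " exceeds the ambient dimension ", V,
                    "; clamped (all units retained)")
        return(x)
    }
    cols <- sort(withSeed(seed, sample.int(V, k)))
    x[, cols, drop = FALSE]
})

#' @rdname randomSubspace
#' @export
setMethod("randomSubspace", "ActivitySet", function(x, k, seed, ...) {
    k <- .assertCount(k, "k")
    V <- nUnits(x)
    if (k >= V) {
        if (k > V)
            warning("k = ", k, " exceeds the ambient dimension ", V,
                    "; clamped (all units retained)")
        return(x)
    }
    rows <- sort(withSeed(seed, sample.int(V, k)))
    x[rows, ]
})

#' Gaussian random projection
#'
#' Multiplies the patterns by a V-by-d matrix of independent
#' \eqn{N(0, 1/d)} entries (the standard Johnson-Lindenstrauss scaling,
#' which preserves squared norms in expectation). Deterministic under the
#' seed. Geometry estimates of low-dimensional manifolds are invariant
#' under projection to a target dimension comfortably above the
#' manifolds' Dimensionality; see \code{\link{convergenceSweep}}.
#'
#' @param x matrix (exemplar-by-unit) or \linkS4class{ActivitySet}.
#' @param d target dimension.
#' @param seed RNG seed for the projection matrix.
#' @param ... unused.
#' @return projected object of the same class, units named
#'   \code{rp1 ... rpd}.
#' @rdname randomProject
#' @export
setMethod("randomProject", "matrix", function(x, d, seed, ...) {
    d <- .assertCount(d, "d")
    V <- ncol(x)
    W <- withSeed(seed, matrix(rnorm(V * d), V, d)) / sqrt(d)
    y <- x %*% W
    colnames(y) <- paste0("rp", seq_len(d))
    y
})

#' @rdname randomProject
#' @export
setMethod("randomProject", "ActivitySet", function(x, d, seed, ...) {
    y <- randomProject(activityPatterns(x), d, seed)
    ActivitySet(y, conceptLabels(x), trials = trialIds(x))
})

#' Convergence sweep over embedding dimensions
#'
#' Recomputes the pairwise geometry over a grid of (random subspace
#' dimension, random projection dimension) settings and reports, per grid
#' point, the mean SNR(m) and mean Signal across ordered concept pairs
#' together with their fraction of the grid maximum. Requested dimensions
#' are clamped to what the data admit: the subspace dimension to the
#' ambient dimension, the projection dimension to the (clamped) subspace
#' dimension; when the projection target is not below the current
#' dimension the projection is skipped, so the largest grid point
#' reproduces the unswept estimate exactly.
#'
#' @param x an \linkS4class{ActivitySet}.
#' @param subspaceDims,projectionDims nonempty integer grids.
#' @param m shot count.
#' @param seed master seed; one sub-seed per grid point and stage.
#' @return data.frame with columns \code{subspace_dim, projection_dim}
#'   (requested), \code{subspace_dim_used, projection_dim_used}
#'   (after clamping), \code{mean_snr, mean_signal, frac_of_max_snr,
#'   frac_of_max_signal}.
#' @export
convergenceSweep <- function(x, subspaceDims, projectionDims, m, seed) {
    if (length(subspaceDims) < 1L || length(projectionDims) < 1L)
        stop("dimension grids must be nonempty")
    grid <- expand.grid(subspace_dim = sort(as.integer(subspaceDims)),
                        projection_dim = sort(as.integer(projectionDims)))
    seeds <- matrix(spawnSeeds(seed, 2L * nrow(grid)), ncol = 2L)
    res <- lapply(seq_len(nrow(grid)), function(i) {
        k <- min(grid$subspace_dim[i], nUnits(x))
        ds <- if (k < nUnits(x))
            randomSubspace(x, k, seeds[i, 1]) else x
        d <- min(grid$projection_dim[i], k)
        if (d < k)
            ds <- randomProject(ds, d, seeds[i, 2])
        gg <- geometryGrid(ds, m)
        data.frame(subspace_dim_used = k, projection_dim_used = d,
                   mean_snr = mean(gg$pairs$snr),
                   mean_signal = mean(gg$pairs$signal))
    })
    out <- cbind(grid, do.call(rbind, res))
    out$frac_of_max_snr <- out$mean_snr / max(out$mean_snr)
    out$frac_of_max_signal <- out$mean_signal / max(out$mean_signal)
    out
}
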