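test_that("estimateManifold recovers centroid and spectrum of simple clouds", {
    # isotropic 4-point configuration in the plane
    X <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    ms <- estimateManifold(X)
    expect_equal(centroid(ms), c(0, 0))
    expect_equal(manifoldRadii(ms)[1], manifoldRadii(ms)[2])
    expect_equal(dimensionality(ms), 2.0)

    # k equal-variance coordinates, all others constant -> D = k
    # (sign designs make the sample covariance exactly isotropic)
    for (k in 2:4) {
        signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
        X <- cbind(signs, matrix(7, nrow(signs), 3))
        ms <- estimateManifold(X)
        expect_equal(dimensionality(ms), k)
        expect_equal(sum(manifoldRadii(ms) > 1e-12), k)
    }
})

test_that("estimateManifold agrees with a brute-force covariance eigendecomposition", {
    set.seed(42)
    X <- matrix(rnorm(20 * 8), 20, 8)
    ms <- estimateManifold(X)
    # independent oracle: eigendecomposition of the exemplar-normalized
    # covariance of the centered data
    Xc <- sweep(X, 2, colMeans(X))
    ev <- eigen(crossprod(Xc) / nrow(X), symmetric = TRUE)
    expect_equal(centroid(ms), colMeans(X), tolerance = 1e-12)
    expect_equal(manifoldRadii(ms)^2, ev$values, tolerance = 1e-8)
    # directions match up to sign
    dots <- abs(colSums(principalDirections(ms) * ev$vectors))
    expect_equal(dots, rep(1, 8), tolerance = 1e-8)
    expect_equal(totalRadiusSq(ms), sum(manifoldRadii(ms)^2))
    expect_equal(dimensionality(ms),
                 sum(ev$values)^2 / sum(ev$values^2), tolerance = 1e-10)
})

test_that("degenerate and undersized inputs are rejected", {
    expect_error(estimateManifold(matrix(1, 1, 4)), "at least 2")
    expect_error(estimateManifold(matrix(3, 10, 4)), "degenerate")
    expect_error(estimateManifold(matrix(c(1, NA, 2, 3), 2, 2)),
                 "missing|finite")
})

test_that("participation ratio has its closed forms", {
    spec <- manifoldSpec(4, centers = cbind(a = rep(0, 4)),
                         spectra = list(c(1, 0.5)), seed = 1)
    expect_equal(dimensionality(groundTruthSummary(spec, "a")), 1.8,
                 tolerance = 1e-15)
    spec2 <- manifoldSpec(10, centers = cbind(a = rep(0, 10)),
                          spectra = list(rep(1, 10)),
                          bases = list(diag(10)))
    expect_identical(dimensionality(groundTruthSummary(spec2, "a")), 10)
})

test_that("self-pair identities hold for random manifolds", {
    for (s in 1:20) {
        ms <- estimateManifold(randomCloud(30, 12, k = 6, seed = s))
        pg <- pairGeometry(ms, ms, m = 5)
        expect_identical(geometricSignal(pg), 0)
        expect_identical(geometricBias(pg), 0)
        expect_lt(abs(overlaps(pg)[["ab"]] - 1 / dimensionality(ms)),
                  1e-10)
    }
})

test_that("disjoint-support manifolds have zero overlaps and closed-form SNR", {
    V <- 12
    I <- diag(V)
    spec <- manifoldSpec(V,
        centers = cbind(a = rep(0, V),
                        b = c(rep(0, 6), 2, 1, rep(0, 4))),
        spectra = list(c(2, 1, 0.5), c(1.5, 1, 0.25)),
        bases = list(I[, 1:3], I[, 4:6]))
    for (m in c(1, 5, 20)) {
        pg <- groundTruthGeometry(spec, "a", "b", m)
        ov <- overlaps(pg)
        expect_equal(unname(ov), c(0, 0, 0))
        S <- geometricSignal(pg); b <- geometricBias(pg)
        Da <- dimensionality(pg)
        expect_equal(geometricSNR(pg),
                     0.5 * (S + b / m) * sqrt(Da * m))
    }
})

test_that("spherical manifolds match the isotropic closed form", {
    V <- 25; delta <- 1.7; lambda <- 0.8
    spec <- sphericalPairSpec(V, delta, lambda)
    pg <- groundTruthGeometry(spec, "a", "b", 5)
    S <- delta^2 / (V * lambda)
    expect_equal(geometricSignal(pg), S, tolerance = 1e-12)
    ov <- overlaps(pg)
    expect_equal(ov[["a"]], S / V, tolerance = 1e-12)
    expect_equal(ov[["b"]], S / V, tolerance = 1e-12)
    expect_equal(ov[["ab"]], 1 / V, tolerance = 1e-12)
    expect_equal(dimensionality(pg), V)
    # brute-force evaluation on explicit bases agrees
    A <- groundTruthSummary(spec, "a")
    B <- groundTruthSummary(spec, "b")
    Ra2 <- sum(lambda * rep(1, V))
    dx <- (centroid(A) - centroid(B)) / sqrt(Ra2)
    Ua <- sweep(principalDirections(A), 2, manifoldRadii(A), `*`) /
        sqrt(Ra2)
    expect_equal(ov[["a"]], sum((t(Ua) %*% dx)^2), tolerance = 1e-12)
})

test_that("ordered pairs are asymmetric and combined overlap matches its definition", {
    msA <- estimateManifold(randomCloud(60, 15, k = 6, seed = 3))
    msB <- estimateManifold(randomCloud(60, 15, k = 8, seed = 4,
                                        center = c(2, rep(0, 14)),
                                        scale = 2))
    ab <- pairGeometry(msA, msB, 5)
    ba <- pairGeometry(msB, msA, 5)
    expect_false(isTRUE(all.equal(geometricSNR(ab), geometricSNR(ba))))
    ov <- overlaps(ab)
    expect_equal(combinedOverlap(ab),
                 (ov[["b"]] + ov[["ab"]]) / 5 + ov[["a"]])
    # combined overlap decreases with m when N^b + N^ab > 0
    ms <- vapply(c(1, 2, 5, 20),
                 function(m) combinedOverlap(pairGeometry(msA, msB, m)),
                 numeric(1))
    expect_true(all(diff(ms) < 0))
    expect_error(pairGeometry(msA, estimateManifold(randomCloud(20, 9)),
                              5), "dimension")
})

test_that("gaussian tail error is the standard normal upper tail", {
    expect_equal(gaussianTailError(0), 0.5)
    expect_lt(gaussianTailError(30), 1e-100)
    expect_equal(gaussianTailError(-30), 1, tolerance = 1e-12)
    z <- seq(-4, 4, by = 0.25)
    expect_equal(gaussianTailError(z) + gaussianTailError(-z),
                 rep(1, length(z)))
    expect_true(all(diff(gaussianTailError(z)) < 0))
    # quadrature oracle at snr = 1
    quad <- integrate(dnorm, 1, Inf, rel.tol = 1e-12)$value
    expect_equal(gaussianTailError(1), quad, tolerance = 1e-10)
    expect_error(gaussianTailError(NaN), "finite")
    expect_error(gaussianTailError(Inf), "finite")
})

test_that("geometry is invariant under global scaling and rotation", {
    set.seed(7)
    V <- 20
    X <- rbind(randomCloud(50, V, k = 5, seed = 10),
               randomCloud(50, V, k = 7, seed = 11,
                           center = c(1.5, rep(0, V - 1))))
    lab <- rep(c("a", "b"), each = 50)
    base <- geometryGrid(ActivitySet(X, lab), m = 5)$pairs
    fields <- c("signal", "bias", "overlap_a", "overlap_b", "overlap_ab",
                "combined_overlap", "snr", "predicted_error",
                "dimensionality_a")
    scaled <- geometryGrid(ActivitySet(3.7 * X, lab), m = 5)$pairs
    Q <- qr.Q(qr(matrix(rnorm(V * V), V, V)))
    rotated <- geometryGrid(ActivitySet(X %*% Q, lab), m = 5)$pairs
    for (f in fields) {
        expect_equal(scaled[[f]], base[[f]], tolerance = 1e-10)
        expect_equal(rotated[[f]], base[[f]], tolerance = 1e-8)
    }
})

test_that("geometryGrid enumerates ordered pairs and flags degenerates", {
    set.seed(5)
    X <- rbind(matrix(rnorm(40), 10, 4), matrix(rnorm(40), 10, 4),
               matrix(rnorm(40), 10, 4))
    ds <- ActivitySet(X, rep(c("u", "v", "w"), each = 10))
    gg <- geometryGrid(ds, m = 5)
    expect_equal(nrow(gg$pairs), 6L)
    expect_setequal(paste(gg$pairs$concept_a, gg$pairs$concept_b),
                    c("u v", "u w", "v u", "v w", "w u", "w v"))
    expect_equal(nrow(gg$concepts), 3L)

    # identical concept clouds -> zero signal for that pair
    X2 <- matrix(rnorm(40), 10, 4)
    ds2 <- ActivitySet(rbind(X2, X2), rep(c("p", "q"), each = 10))
    gg2 <- geometryGrid(ds2, m = 5)
    expect_equal(gg2$pairs$signal, c(0, 0))

    # degenerate concept excluded with a warning
    X3 <- rbind(X2, matrix(1, 10, 4))
    ds3 <- ActivitySet(rbind(X3, X2),
                       rep(c("p", "flat", "q"), each = 10))
    expect_warning(gg3 <- geometryGrid(ds3, m = 5), "flat")
    expect_equal(sort(unique(gg3$pairs$concept_a)), c("p", "q"))
})

test_that("project2D builds the signal plane", {
    set.seed(9)
    V <- 15; delta <- 4
    Xa <- matrix(rnorm(200 * V), 200, V)
    Xb <- matrix(rnorm(200 * V), 200, V)
    Xb[, 3] <- Xb[, 3] + delta
    ds <- ActivitySet(rbind(Xa, Xb), rep(c("a", "b"), each = 200))
    pr <- project2D(ds, "a", "b")
    expect_equal(unname(crossprod(pr$axes)), diag(2),
                 tolerance = 1e-10)
    centerDist <- sqrt(sum((colMeans(Xa) - colMeans(Xb))^2))
    expect_equal(abs(diff(pr$centroids$x)), centerDist,
                 tolerance = 1e-10)
    expect_equal(centerDist, delta, tolerance = 0.1)
    expect_equal(pr$centroids$y, c(0, 0), tolerance = 1e-8)
    # the y-axis maximizes residual variance: beat random orthogonal
    # directions
    pooled <- rbind(Xa, Xb)
    pc <- sweep(pooled, 2, colMeans(pooled))
    vy <- var(pc %*% pr$axes[, 2])
    xax <- pr$axes[, 1]
    for (i in 1:200) {
        u <- rnorm(V)
        u <- u - sum(u * xax) * xax
        u <- u / sqrt(sum(u^2))
        expect_lte(drop(var(pc %*% u)), vy + 1e-10)
    }
    expect_error(project2D(ds, "a", "a"), "coincident")
})
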