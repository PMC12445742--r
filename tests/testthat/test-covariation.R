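# build a pair table exactly obeying log N = alpha log S + beta log D +
# gamma, with optional gaussian noise on log N
loglinearPairs <- function(n, alpha, beta, gamma, sigma = 0, seed = 1) {
    set.seed(seed)
    S <- exp(runif(n, -3, 1))
    D <- exp(runif(n, 0.5, 3.5))
    N <- exp(alpha * log(S) + beta * log(D) + gamma +
                 rnorm(n, sd = sigma))
    data.frame(signal = S, dimensionality_a = D, combined_overlap = N,
               m = 5L)
}

test_that("the log-linear overlap fit is exact on noiseless data", {
    tab <- loglinearPairs(60, alpha = 0.9, beta = -1.4, gamma = -0.7)
    fit <- fitLogLinearOverlap(tab)
    expect_equal(fit@alpha, 0.9, tolerance = 1e-8)
    expect_equal(fit@beta, -1.4, tolerance = 1e-8)
    expect_equal(fit@gamma, -0.7, tolerance = 1e-8)
    expect_gt(fit@rSquared, 1 - 1e-10)
    expect_lt(fit@rSquaredSignalOnly, fit@rSquared)
    expect_equal(fit@nPoints, 60L)
})

test_that("the noisy log-linear fit recovers coefficients within OLS error", {
    tab <- loglinearPairs(500, alpha = 0.9, beta = -1.4, gamma = -0.7,
                          sigma = 0.1, seed = 2)
    fit <- fitLogLinearOverlap(tab)
    expect_lt(abs(fit@alpha - 0.9), 3 * fit@coefSe[["alpha"]])
    expect_lt(abs(fit@beta + 1.4), 3 * fit@coefSe[["beta"]])
    expect_lt(abs(fit@gamma + 0.7), 3 * fit@coefSe[["gamma"]])
    expect_gt(fit@rSquared, 0.9)
})

test_that("nonpositive pairs are excluded and degenerate designs rejected", {
    tab <- loglinearPairs(20, 1, -1, 0)
    tab$combined_overlap[c(3, 7)] <- 0
    expect_warning(fit <- fitLogLinearOverlap(tab), "excluded")
    expect_equal(fit@nPoints, 18L)
    expect_equal(fit@nExcluded, 2L)
    const <- loglinearPairs(20, 1, -1, 0)
    const$signal <- 1           # constant log S: rank deficient
    expect_error(fitLogLinearOverlap(const), "rank-deficient")
    expect_error(fitLogLinearOverlap(loglinearPairs(2, 1, -1, 0)),
                 "at least 3")
})

test_that("the snr surface reduces to the overlap-free closed form", {
    # gamma -> -inf emulates a vanishing fitted overlap
    fit <- new("LogLinearFit", alpha = 1, beta = -1, gamma = -80,
               coefSe = c(gamma = 0, alpha = 0, beta = 0), rSquared = 1,
               rSquaredSignalOnly = 1, m = 5L, nPoints = 10L,
               nExcluded = 0L)
    s <- exp(seq(log(0.05), log(2), length = 15))
    d <- exp(seq(log(2), log(40), length = 15))
    surf <- snrSurface(fit, bias = 0, sGrid = s, dGrid = d)
    expect_equal(surf$surface,
                 outer(s, d, function(S, D) 0.5 * S * sqrt(D * 5)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # iso-SNR lines obey S ~ D^(-1/2) in log-log space
    iso <- vapply(d, function(D) {
        uniroot(function(S) 0.5 * S * sqrt(D * 5) - 1, c(1e-8, 1e3),
                tol = 1e-12)$root
    }, numeric(1))
    slope <- diff(log(iso)) / diff(log(d))
    expect_equal(slope, rep(-0.5, 14), tolerance = 1e-6)
    expect_error(snrSurface(fit, 0, sGrid = c(-1, 1), dGrid = d),
                 "positive")
})

test_that("the snr surface equals a direct evaluation with the fitted overlap", {
    tab <- loglinearPairs(100, alpha = 0.8, beta = -1.2, gamma = -0.5,
                          sigma = 0.05, seed = 3)
    fit <- fitLogLinearOverlap(tab)
    sGrid <- c(0.1, 0.5, 1.5)
    dGrid <- c(3, 10, 30)
    surf <- snrSurface(fit, bias = 0.2, sGrid = sGrid, dGrid = dGrid)
    S <- 0.5; D <- 10
    Nhat <- exp(fit@gamma) * S^fit@alpha * D^fit@beta
    direct <- 0.5 * (S + 0.2 / 5) / sqrt(1 / (D * 5) + Nhat)
    expect_equal(surf$surface[2, 2], direct, ignore_attr = TRUE)

    # iso-SNR lines are slightly curved in log-log space when
    # beta != -2 alpha
    dFine <- exp(seq(log(3), log(30), length = 9))
    level <- surf$surface[2, 2]
    isoS <- vapply(dFine, function(D) {
        f <- function(S) {
            Nh <- exp(fit@gamma) * S^fit@alpha * D^fit@beta
            0.5 * (S + 0.2 / 5) / sqrt(1 / (D * 5) + Nh) - level
        }
        uniroot(f, c(1e-8, 1e4), tol = 1e-13)$root
    }, numeric(1))
    curv <- diff(diff(log(isoS)))
    expect_gt(max(abs(curv)), 1e-4)
})

test_that("permutation correlation handles exact and null cases", {
    x <- rnorm(30)
    pc <- pearsonPermutation(x, x, nPermutations = 500, seed = 1)
    expect_equal(pc@rho, 1.0)
    expect_equal(pc@pValue, 1 / 501)
    pc2 <- pearsonPermutation(x, -x, nPermutations = 500, seed = 1)
    expect_equal(pc2@rho, -1.0)
    expect_equal(pc2@pValue, 1 / 501)
    expect_error(pearsonPermutation(rep(1, 10), rnorm(10)), "constant")
    expect_error(pearsonPermutation(1:2, 1:2), "length")
    # permutation p agrees with the observed-rank definition
    set.seed(5)
    a <- rnorm(25); b <- 0.4 * a + rnorm(25)
    pc3 <- pearsonPermutation(a, b, nPermutations = 400, seed = 9)
    set.seed(9)
    P <- vapply(1:400, function(i) sample.int(25), integer(25))
    rperm <- apply(P, 2, function(p) cor(a, b[p]))
    expect_equal(pc3@pValue,
                 (1 + sum(abs(rperm) >= abs(pc3@rho))) / 401)
})

test_that("property correlations identify coordinated and antagonistic sweeps", {
    # levels in which only Signal varies: corr(S, SNR) = 1
    S <- seq(0.2, 2, length = 10)
    D <- rep(8, 10); N <- rep(0.02, 10); b <- rep(0.1, 10)
    snr <- 0.5 * (S + b / 5) / sqrt(1 / (D * 5) + N)
    geo <- data.frame(level = seq_len(10), snr = snr, signal = S,
                      bias = b, combined_overlap = N,
                      dimensionality_a = D)
    suppressWarnings(
        cs <- propertyCorrelationSuite(geo, "perLevelAverage",
                                       nPermutations = 200, seed = 3))
    expect_equal(cs$correlation["snr", "signal"], 1.0)
    expect_true(is.na(cs$correlation["snr", "bias"]))
    expect_equal(cs$correlation, t(cs$correlation))
    expect_equal(unname(diag(cs$correlation)), rep(1, 5))

    # levels sliding along an iso-SNR contour: S and D antagonistic,
    # SNR flat
    Dn <- exp(seq(log(3), log(30), length = 40))
    Sn <- vapply(Dn, function(DD) {
        uniroot(function(SS) 0.5 * SS * sqrt(DD * 5) - 1,
                c(1e-8, 1e3), tol = 1e-12)$root
    }, numeric(1))
    set.seed(11)
    Nn <- 1e-4 * exp(rnorm(40, sd = 0.3))
    # small independent measurement jitter around the common SNR level
    snrN <- exp(rnorm(40, sd = 0.01))
    geo2 <- data.frame(level = seq_len(40), snr = snrN, signal = Sn,
                       bias = rnorm(40, 0, 0.01),
                       combined_overlap = Nn, dimensionality_a = Dn)
    cs2 <- propertyCorrelationSuite(geo2, "perLevelAverage",
                                    nPermutations = 200, seed = 4)
    expect_lt(cs2$correlation["signal", "dimensionality"], -0.9)
    expect_lt(abs(cs2$correlation["signal", "snr"]), 0.5)
    expect_true(all(cs2$pValue[upper.tri(cs2$pValue)] >= 1 / 201))

    # per-pair mode and depth filtering
    geo2$level_fraction <- rep(seq(0, 1, length = 8), each = 5)
    cs3 <- propertyCorrelationSuite(geo2, "perPair",
                                    nPermutations = 100, seed = 5,
                                    levelFractionRange = c(0, 0.45))
    expect_equal(cs3$n, 20L)
    geoFew <- geo2[1:5, ]
    geoFew$level <- c(1, 1, 2, 2, 2)
    expect_error(propertyCorrelationSuite(geoFew, "perLevelAverage"),
                 "3 levels")
})

test_that("hierarchy hop distances match breadth-first search", {
    edges <- data.frame(parent = c("root", "root", "animal", "animal",
                                   "plant"),
                        child = c("animal", "plant", "dog", "cat",
                                  "tree"))
    d <- hierarchyPathDistance(edges)
    expect_equal(d["dog", "dog"], 0)
    expect_equal(d["animal", "dog"], 1)
    expect_equal(d["dog", "cat"], 2)
    expect_equal(d["dog", "tree"], 4)
    expect_equal(d, t(d))

    # random tree versus an independent BFS oracle
    set.seed(6)
    n <- 50
    parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1),
                           integer(1)))
    tre <- data.frame(parent = paste0("n", parent[-1]),
                      child = paste0("n", 2:n))
    d2 <- hierarchyPathDistance(tre)
    adj <- lapply(seq_len(n), function(i) integer(0))
    for (i in 2:n) {
        adj[[i]] <- c(adj[[i]], parent[i])
        adj[[parent[i]]] <- c(adj[[parent[i]]], i)
    }
    bfs <- function(s) {
        dist <- rep(NA_integer_, n)
        dist[s] <- 0L
        q <- s
        while (length(q)) {
            v <- q[1]; q <- q[-1]
            for (w in adj[[v]]) if (is.na(dist[w])) {
                dist[w] <- dist[v] + 1L
                q <- c(q, w)
            }
        }
        dist
    }
    lab <- paste0("n", seq_len(n))
    for (s in c(1, 7, 23)) {
        expect_equal(unname(d2[lab[s], lab]), as.numeric(bfs(s)))
    }
    expect_error(hierarchyPathDistance(edges, c("dog", "unknown")),
                 "unknown")
    disc <- rbind(edges, data.frame(parent = "x", child = "y"))
    expect_warning(d3 <- hierarchyPathDistance(disc), "disconnected")
    expect_true(is.infinite(d3["dog", "y"]))
})
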