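# Shared fixture builders; everything is generated in code under fixed
# seeds.

# a random exemplar cloud with anisotropic low-rank structure
randomCloud <- function(P, V, k = min(5L, V), seed = 1L,
                        scale = 1, center = rep(0, V)) {
    set.seed(seed)
    B <- qr.Q(qr(matrix(rnorm(V * k), V, k)))
    lam <- sort(runif(k, 0.3, 2), decreasing = TRUE) * scale
    Z <- matrix(rnorm(P * k), P, k)
    sweep(Z, 2, sqrt(lam), `*`) %*% t(B) +
        matrix(center, P, V, byrow = TRUE)
}

# two-concept spec of isotropic (spherical) manifolds separated along
# the first axis
sphericalPairSpec <- function(V, delta, lambda = 1, P = 200L, seed = 1L) {
    manifoldSpec(ambientDim = V,
                 centers = cbind(a = rep(0, V),
                                 b = c(delta, rep(0, V - 1))),
                 spectra = list(rep(lambda, V), rep(lambda, V)),
                 bases = list(diag(V), diag(V)),
                 exemplarCount = P)
}

# center separation of an isotropic V-dim pair achieving a target
# geometric SNR(m); closed form inverted numerically
sphericalDeltaForSNR <- function(targetSnr, V, lambda = 1, m = 5) {
    if (targetSnr == 0) return(0)
    f <- function(S)
        0.5 * S / sqrt((2 / V + S / V) / m + S / V) - targetSnr
    S <- uniroot(f, c(1e-9, 1e6), tol = 1e-12)$root
    sqrt(S * V * lambda)
}

# spec with two random low-rank manifolds in a common ambient space
lowRankPairSpec <- function(V, k, sep = 1, P = 150L, seed = 1L,
                            lambdaMax = 2) {
    set.seed(seed)
    lamA <- sort(runif(k, 0.2, lambdaMax), decreasing = TRUE)
    lamB <- sort(runif(k, 0.2, lambdaMax), decreasing = TRUE)
    dir <- rnorm(V); dir <- dir / sqrt(sum(dir^2))
    manifoldSpec(ambientDim = V,
                 centers = cbind(a = rep(0, V), b = sep * dir),
                 spectra = list(lamA, lamB),
                 exemplarCount = P, seed = seed + 1L)
}

expect_rel_equal <- function(actual, expected, tol) {
    expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)),
              tol)
}
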