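# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old))
                rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    expr
}

# Deterministic table of independent sub-seeds spawned from a master
# seed; used so that nested resampling loops are reproducible and
# order-independent (each fold runs under its own stream).
spawnSeeds <- function(seed, n) {
    withSeed(seed, sample.int(2147483646L, n))
}

.assertCount <- function(x, name) {
    if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
        stop("'", name, "' must be a positive integer")
    as.integer(x)
}

.assertPatternMatrix <- function(x) {
    x <- as.matrix(x)
    if (!is.numeric(x))
        stop("activity patterns must be numeric")
    if (any(!is.finite(x)))
        stop("activity patterns contain missing or non-finite values")
    x
}
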