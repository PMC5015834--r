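# Seed hygiene: every stochastic operation takes an explicit seed and
# restores the caller's RNG state on exit.

withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old))
                rm(".Random.seed", envir = globalenv())
            else
                assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    expr
}

# deterministic stream of sub-seeds below 2^31 derived from one master seed
deriveSeeds <- function(seed, n) {
    withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}
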