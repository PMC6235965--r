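# Internal helpers: seeded evaluation, frame-grid rounding, child seeds.

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
    force(expr)
}

# Smallest grid point k/fps that is >= t (tolerating float slop).
ceilToGrid <- function(t, dt) {
    dt * ceiling(t / dt - 1e-9)
}

# Counter-based child seeds: adding modules never perturbs existing streams.
childSeed <- function(seed, index) {
    as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 104729) %%
               2147483647)
}
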