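# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user seeds.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("seed must be a single integer", call. = FALSE)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Column-standardise a matrix; constant columns are centred but left unscaled
# so they do not blow up to NaN.
zscore <- function(m) {
    mu <- colMeans(m)
    sd <- apply(m, 2L, stats::sd)
    sd[!is.finite(sd) | sd == 0] <- 1
    sweep(sweep(m, 2L, mu, "-"), 2L, sd, "/")
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Deterministic label makers: snp001 ..., iso001 ..., etc.
makeLabels <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
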