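# Internal helpers shared across modules.

# Deterministic child seed from a master seed and a stage offset, kept below
# 2^31 so it is always a valid R integer seed.
deriveSeed <- function(seed, offset) {
    as.integer(((as.numeric(seed) %% 65536) * 31013 +
                as.numeric(offset) * 7919 + 104729) %% 2147483647)
}

# Evaluate `code` under `seed` without clobbering the caller's RNG stream.
withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

assertScalarNumeric <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stop("'", name, "' must be a single non-missing number",
             call. = FALSE)
    invisible(x)
}

assertCount <- function(x, name, positive = FALSE) {
    assertScalarNumeric(x, name)
    if (x %% 1 != 0 || x < if (positive) 1 else 0)
        stop("'", name, "' must be a ", if (positive) "positive " else
             "non-negative ", "integer", call. = FALSE)
    invisible(as.integer(x))
}

# Zero-truncated Poisson draws with underlying mean `mu` (the reported mean
# is the Poisson parameter before truncation).
rztpois <- function(n, mu) {
    if (n == 0L) return(integer(0))
    p0 <- stats::dpois(0, mu)
    stats::qpois(p0 + stats::runif(n) * (1 - p0), mu)
}

randomDNA <- function(n, len) {
    if (n == 0L) return(character(0))
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""),
        character(1))
}
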