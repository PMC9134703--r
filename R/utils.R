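# internal helpers shared across modules

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

checkScalarNumeric <- function(x, name, finite = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
        stopf("'%s' must be a finite numeric scalar", name)
    invisible(x)
}

# Wald 95% CI bounds for an estimate table
waldCI <- function(beta, se, level = 0.95) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    cbind(lower = beta - z * se, upper = beta + z * se)
}
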