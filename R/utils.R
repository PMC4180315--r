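# Run expr with a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards so package functions never perturb user code.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

stopIfNot01 <- function(x, what) {
    if (any(!is.na(x) & (x < 0 | x > 1)))
        stop(what, " must lie in [0,1]", call. = FALSE)
    invisible(x)
}

# single structured log line per pipeline stage
stageLog <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
}
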