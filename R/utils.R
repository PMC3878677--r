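# RNG plumbing shared by the generator, learner and evaluation code.

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

#' Derive a stream-specific seed from a base seed
#'
#' Deterministic integer hash used to give every LOOCV split, permutation and
#' ensemble run its own reproducible seed without coupling their random
#' streams. Always below 2^31.
#'
#' @param base integer base seed.
#' @param index nonnegative integer stream index.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(base, index) {
    base <- as.double(base) %% 2147483647
    index <- as.double(index) %% 65536
    as.integer((base + 2654435761 * index) %% 2147483647)
}

# Format an accuracy fraction the way the study's tables print it: percent to
# one decimal place.
#' Format an accuracy as a percentage
#'
#' @param accuracy fraction in [0, 1].
#' @return character, e.g. `formatAccuracy(18/23)` is `"78.3%"`.
#' @export
formatAccuracy <- function(accuracy) {
    sprintf("%.1f%%", 100 * accuracy)
}
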