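# internal helpers

# round half away from zero is not wanted; the windowing contract is round
# half *up* (toward +Inf), reproducible across platforms
round_half_up <- function(x) floor(x + 0.5)

# evaluate `code` under a local RNG state; the caller's stream is untouched
with_seed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) {
            assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    })
    set.seed(seed)
    force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Mixes a master seed with any number of integer coordinates (section,
#' phase, mode, cycle, ...) so that every cell of an experimental design
#' gets its own stable seed and adding cells never perturbs existing ones.
#'
#' @param master integer master seed.
#' @param ... integer coordinates identifying the design cell.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
    xs <- c(master, ...)
    h <- 0
    for (x in xs) {
        h <- (h * 1000003 + (as.numeric(x) %% 2147483647)) %% 2147483647
    }
    as.integer(h)
}

stop_if_not_scalar_pos <- function(x, name, allow_zero = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
        (if (allow_zero) x >= 0 else x > 0)
    if (!ok) stop(sprintf("`%s` must be a %s finite scalar", name,
                          if (allow_zero) "non-negative" else "positive"),
                  call. = FALSE)
    invisible(x)
}
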