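#' Derive a stage-specific child seed from a global seed
#'
#' Stable integer derivation so that pipeline stages can be re-run in
#' isolation while still fanning out from one global seed. The result is
#' always a positive integer below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param label character tag naming the stage (and optionally an index).
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(42, "simulate")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  child <- (abs(as.double(seed)) %% 2147483647) * 48271 + h
  as.integer(child %% 2147483629 + 1)
}

# evaluate expr under a local RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
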