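#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one integer seed; stages, subjects
#' and sessions get decorrelated sub-streams by hashing the master seed with a
#' list of small integer tags. The result always lies in `[0, 2^31 - 2]` so it
#' is a valid `set.seed()` argument on 32-bit-integer R.
#'
#' @param seed master integer seed.
#' @param ... integer tags (e.g. subject index, session index).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (v in tags) {
    # 64-bit-safe modular mix in double arithmetic (exact below 2^53)
    h <- (h * 69069 + as.numeric(v) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
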