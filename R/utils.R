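# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' `.Random.seed` afterwards, so seeded generators never leak state into the
#' caller's RNG stream. With `seed = NULL` the expression uses (and advances)
#' the current stream.
#'
#' @param seed integer scalar or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# assert helper: stop with the caller-supplied message when cond is not
# a single TRUE
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# scalar numeric check
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# short deterministic hex digest of an R object (config fingerprinting for
# report provenance; not cryptographic)
object_hash <- function(x) {
  raw <- as.integer(serialize(x, connection = NULL, version = 2L))
  h <- 0
  for (b in raw) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
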