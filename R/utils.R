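#' Derive a child seed from a master seed and a string tag
#'
#' Stable 31-bit hash so that per-tissue / per-stage RNG streams do not depend
#' on the order in which objects are generated. Polynomial rolling hash of the
#' tag folded into the master seed, reduced modulo 2^31 - 1.
#'
#' @param seed master integer seed
#' @param ... character or numeric tags identifying the stream
#' @return an integer in [1, 2^31 - 2]
#' @export
derive_seed <- function(seed, ...) {
  tag <- paste(vapply(list(...), function(x) paste(format(x), collapse = "|"),
                      character(1)), collapse = "/")
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(tag)) h <- (h * 131 + code) %% m
  as.integer(h %% (m - 2L) + 1L)
}

#' Evaluate an expression with a locally-scoped RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not disturb the
#' caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
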