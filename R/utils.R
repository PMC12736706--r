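#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the current RNG state, seeds it, evaluates `code`, and restores the
#' state on exit, so seeded operations never disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# derive k reproducible sub-seeds (< 2^31) from one master seed
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' FNV-1a hash of an R object (config provenance stamping)
#'
#' @param x Any serialisable object.
#' @return Hex string.
#' @keywords internal
fnv1a_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2))
  h <- 216613626
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647   # polynomial rolling hash, fits a double
  }
  sprintf("%08x", as.integer(h))
}

stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}
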