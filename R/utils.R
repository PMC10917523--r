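#  Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local, seeded RNG state
#'
#' Saves and restores `.Random.seed` so that seeded generators never disturb
#' (and are never disturbed by) the caller's RNG stream. All randomness in the
#' package flows through this helper with an explicit seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

# derive a stream seed from a base seed; keeps results < 2^31
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629 + 1
}

# min-max normalization to [0, 1]; constant input maps to all zeros
minmax <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] <= r[1]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

is_prob <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 0 && x <= 1

# disc-shaped logical brush with odd side; wraps EBImage::makeBrush
disc_brush <- function(radius) {
  if (radius < 1) return(matrix(1, 1, 1))
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}
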