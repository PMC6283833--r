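# Seed discipline shared by every stochastic operation in the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds R's Mersenne-Twister generator with
#' `seed`, evaluates `expr`, and restores the previous state, so no function
#' in the package leaks hidden global RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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

#' Derive a child seed from a master seed and an index
#'
#' Deterministic counter scheme used whenever one seeded operation needs many
#' independent sub-streams (per-patch seeds, per-batch-item mask seeds, ...):
#' `(seed * 48271 + index) mod (2^31 - 1)`. The multiplier is the MINSTD LCG
#' constant; products stay below 2^53 so the arithmetic is exact in doubles.
#'
#' @param seed Integer master seed.
#' @param index Non-negative integer counter.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  s <- as.double(seed) %% 2147483647
  as.integer((s * 48271 + as.double(index)) %% 2147483647)
}

# clip a numeric object into [lo, hi]
clip_range <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}
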