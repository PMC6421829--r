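#' Derive a reproducible child seed
#'
#' Deterministically maps a (global seed, index) pair to a child seed so that
#' every iteration of a repeated-rarefaction or replicate loop has its own
#' reproducible random stream. The map is a fixed affine congruence; children
#' are always in `[1, 2^31 - 19]` and identical across platforms.
#'
#' @param seed integer global seed.
#' @param index non-negative integer iteration index (vectorised).
#' @return integer vector of child seeds.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # all intermediates stay far below 2^53, so double arithmetic is exact
  as.integer(((seed %% 1000003) * 2011 + index * 7919) %% 2147483629 + 1)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# global .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  old <- get0(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a message assembled sprintf-style, no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
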