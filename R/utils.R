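# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian sigma from full width at half maximum
fwhm_to_sigma <- function(fwhm) fwhm / sqrt(8 * log(2))

# deterministic sub-seed derivation; keeps results independent across stages
# while everything traces back to one user-visible seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1009) %% 2147483587L)
}

# run code under a temporary seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) rlang::abort(sprintf(fmt, ...))

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a single finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}
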