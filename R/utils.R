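#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' then restores the previous RNG state, so no package function ever leaks
#' randomness into (or depends on) the caller's global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic sub-seed derivation; keeps results < 2^31 so they remain
# valid R integer seeds. The combined seed is passed through two rounds of
# generator output: a plain linear combination leaves enough structure in
# the generator's (linearly scrambled) initial state that streams derived
# from related (seed, k) pairs can be statistically dependent.
derive_seed <- function(seed, k) {
  base <- as.integer((as.numeric(seed) * 1103515245 + as.numeric(k) * 12345) %%
                       2147483629)
  once <- with_seed(base, sample.int(2147483647L, 1L))
  with_seed(once, sample.int(2147483647L, 1L))
}

#' Round half away from zero
#'
#' Reporting convention used for all printed percentages and summary
#' statistics: round to `digits` decimals with halves moving away from zero
#' (so 0.125 -> 0.13), unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

stopifnot_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %s", name, min), call. = FALSE)
  }
}
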