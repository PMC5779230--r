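# Shared validation and seeding helpers.

# All generators take an integer `seed`; nested stages derive their own
# sub-seeds with `derive_seed()` so one pipeline seed reproduces everything.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the previous RNG state, so
#' seeded simulations do not disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0) {
  assert_scalar_num(x, name, lower = lower)
  if (x != round(x)) abort(sprintf("`%s` must be an integer count.", name))
  invisible(as.integer(x))
}

# Largest-remainder allocation of n among classes with target fractions.
# Deterministic so small cohorts are exactly reproducible.
largest_remainder <- function(n, fractions) {
  stopifnot(!is.null(names(fractions)))
  if (abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must sum to 1.")
  }
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}
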