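# Internal helpers shared across modules.

#' @importFrom rlang abort warn %||%
#' @importFrom stats var sd cor median quantile rnorm runif setNames
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministic per-unit substream seeds derived from a base seed.
# Unit i always maps to the same seed, so enlarging a cohort never
# perturbs the draws of earlier subjects.
split_seed <- function(seed, index, salt = 0L) {
  ((as.double(seed) * 48271 + as.double(index) * 9973 + salt) %% 2147483629) + 1
}

assert_prob_vector <- function(p, what, tol = 1e-9) {
  if (any(p < 0) || abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must be a non-negative vector summing to 1 (got sum %.12g).",
                  what, sum(p)))
  }
  invisible(p)
}

# Round half away from zero to `digits` decimals (printed-table convention).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
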