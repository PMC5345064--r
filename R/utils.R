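#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats rbinom rgeom rexp rpois runif setNames density median
#'   ks.test binom.test psignrank pnorm var sd
#' @importFrom utils head tail
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never clobber user streams.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
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
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stream index,
# kept below 2^31 so it is always a valid R integer.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + 11 * stream) %% 2147483629
}

# Named-lookup helper: value from a named vector, or `default` when absent.
`%|na|%` <- function(x, default) {
  if (length(x) != 1L || is.na(x)) default else x
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
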