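# Internal helpers shared across modules.

# Draw `n` independent sub-seeds from a master seed without disturbing the
# caller's RNG state. Sub-seeds index independent substreams for e.g. the
# repeated splits, stability subsamples and permutations of the ML module.
derive_seeds <- function(seed, n, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(salt) * 7919L) %% 2147483629L)
  sample.int(2147483646L, n)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

logit2 <- function(p) log2(p / (1 - p))
expit2 <- function(m) 2^m / (1 + 2^m)
logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

# Beta values are clipped into this range everywhere they are emitted, so the
# logit/M transforms stay finite.
BETA_MIN <- 0.001
BETA_MAX <- 0.999

clip_beta <- function(b) pmin(pmax(b, BETA_MIN), BETA_MAX)

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}
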