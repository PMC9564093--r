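# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# user's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Spawn child seeds from one master seed
#'
#' Draws `n` distinct integer seeds (all below 2^31 - 1) from a temporary
#' RNG stream seeded with `seed`, without disturbing the caller's RNG state.
#' Used to give every participant, block and sampler its own reproducible
#' stream.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return An integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n, replace = FALSE))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Map angular residuals to (-pi, pi].
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# package-level cache for lattices and density normalisations
.hg_cache <- new.env(parent = emptyenv())
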