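# Deterministic seed derivation for nested Monte Carlo streams.
#
# A master seed plus a sequence of string/integer labels is hashed to a seed
# in [1, 2^31 - 2] with a Lehmer-style polynomial string hash. Streams are
# keyed by label so that e.g. the distance stream of outer replication i is
# the same whichever policy consumes it (enabling common random numbers),
# and adding a policy never perturbs another policy's draws.

derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  s <- paste(c(format(master, scientific = FALSE), ...), collapse = "\x1f")
  h <- 0
  for (b in utf8ToInt(s)) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# Run `expr` under a temporary RNG state seeded by `seed` (NULL = leave the
# global stream alone).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
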