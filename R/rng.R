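# Deterministic sub-seed derivation.
#
# Every stochastic stage (structure, CPTs, sampling, amputation, learners) gets
# its own seed derived from a master seed plus a stage label, so factorial
# experiments are reproducible and replicates are independent of execution
# order.

#' Derive a reproducible sub-seed
#'
#' Mixes a master seed with a stage label and optional integer indices into a
#' new seed in `[1, 2^31 - 2]`. The map is a fixed integer hash (splitmix-like
#' multiply-xor carried out in double precision), so the same inputs always
#' give the same sub-seed on every platform.
#'
#' @param seed Integer master seed.
#' @param label Character stage label (e.g. `"cpts"`, `"ampute"`).
#' @param ... Additional integer indices (replicate number, repeat number).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label = "", ...) {
  m <- 2147483629 # prime < 2^31
  h <- as.double(seed %% m)
  mix <- function(h, v) {
    # Horner-style accumulation; doubles hold exact integers < 2^53 so the
    # intermediate products (< m * 69069) never lose precision.
    ((h * 69069 + v + 12345) %% m)
  }
  if (nzchar(label)) {
    for (v in utf8ToInt(label)) h <- mix(h, v)
  }
  for (v in c(...)) h <- mix(h, as.double(v))
  as.integer(h %% 2147483646) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
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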