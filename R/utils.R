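# Internal helpers: seeded RNG scoping and stage-seed derivation.

#' Derive a reproducible stage seed from a global seed
#'
#' A single pipeline seed deterministically fans out into one seed per
#' stage, so any stage can be rerun in isolation and reproduce its part of
#' a full run. The derivation hashes the stage name onto the global seed
#' and keeps the result in the 32-bit signed integer range R requires.
#'
#' @param seed integer global seed.
#' @param stage character stage name (e.g. `"split"`, `"iwd"`).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 1000003
  as.integer((abs(seed) %% 1000003) * 2038 + h) %% .Machine$integer.max
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers user-level randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# stopifnot-with-message
fail_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
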