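# Deterministic seed streams.
#
# All randomness in the package flows from one master seed. Named sub-streams
# (e.g. per chromosome, per window) are derived by hashing the stream tag into
# a 31-bit integer, so fixtures are reproducible and independent stages do not
# perturb each other's draws.

.SEED_MOD <- 2147483647 # 2^31 - 1, keeps derived seeds valid R integers

#' Derive a reproducible sub-seed from a master seed and a stream tag
#'
#' @param master integer master seed.
#' @param tag character scalar naming the stream (e.g. "chr3/win12").
#' @return an integer in [1, 2^31 - 2], a pure function of (master, tag).
#' @export
derive_seed <- function(master, tag) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(tag),
            length(tag) == 1L)
  h <- as.double(master %% .SEED_MOD)
  for (code in utf8ToInt(tag)) {
    # 31-bit multiplicative hash; doubles are exact below 2^53
    h <- (h * 31 + code) %% .SEED_MOD
  }
  as.integer(h %% (.SEED_MOD - 2) + 1)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores .Random.seed so seeded helpers do not disturb the
#' caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  expr
}
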