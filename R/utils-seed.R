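# Single-seed reproducibility plumbing. Every stochastic entry point takes an
# integer seed; nested stages derive sub-seeds by hashing (seed, label) so no
# two stages share a stream and no function touches the caller's RNG state.

#' Derive a stage-specific sub-seed from a master seed
#'
#' Deterministic 31-ary string hash of `label` folded into `seed`, reduced
#' modulo 2^31 - 1 so the result is always a valid `set.seed()` input.
#'
#' @param seed Integer master seed.
#' @param label Character stage label.
#' @return A single non-negative integer below 2^31 - 1.
#' @export
#' @examples
#' deriveSeed(1L, "scan")
deriveSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- abs(as.double(seed)) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% 2147483647L)
  force(code)
}
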