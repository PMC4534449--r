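#' Derive a stage-specific random seed from a root seed
#'
#' All stochastic stages of the pipeline draw their randomness from one root
#' seed through this splitting scheme, so that stages can be re-run in
#' isolation (or resumed) and still reproduce a full run bit for bit. The
#' derived seed is `(root * 2654435761 + hash(label)) mod (2^31 - 1)` where
#' `hash` is a polynomial (base-31) hash of the label's UTF-8 code points —
#' i.e. a deterministic, documented function of `(root, label)` that stays
#' within R's 32-bit integer range.
#'
#' @param root integer root seed.
#' @param label character scalar naming the consumer (e.g. `"landscape"`,
#'   `"occupancy"`, `"background"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root, label) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 31 + cp) %% m
  as.integer((abs(root) %% m * 2654435761 %% m + h) %% m)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
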