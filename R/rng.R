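#' @keywords internal
"_PACKAGE"

# Deterministic named substreams. Every stochastic routine derives its own
# 31-bit seed from a base seed plus a label path, so that e.g. adding
# participants to a cohort never perturbs the draws of existing ones.

MOD31 <- 2147483647

#' Derive a substream seed from a base seed and a label path
#'
#' Folds the base seed and an arbitrary sequence of integer or character
#' labels into a single seed below 2^31 using a multiplicative hash. The
#' same `(seed, ...)` path always yields the same substream seed; distinct
#' paths are (for practical purposes) independent.
#'
#' @param seed Integer base seed.
#' @param ... Integer or character labels identifying the substream
#'   (e.g. participant id, session, condition, stage name).
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(1, "svt", 3, "test")
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- (abs(as.numeric(seed)) %% MOD31)
  for (p in list(...)) {
    codes <- if (is.character(p)) utf8ToInt(paste(p, collapse = "\x1f")) else as.numeric(p)
    for (x in codes) {
      h <- (h * 69069 + (abs(x) %% MOD31) + 1) %% MOD31
    }
  }
  as.integer(h)
}

# Evaluate `expr` under the substream's RNG state, restoring the caller's
# state afterwards.
with_substream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, ...))
  expr
}
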