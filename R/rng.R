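#' Derive a named sub-seed from a master seed
#'
#' Every stochastic stage of the simulator draws from its own substream,
#' derived deterministically from the master seed and a stage name. Changing
#' the draws of one stage therefore never perturbs another stage's stream.
#'
#' The derivation hashes the stage name with a small splitmix-style integer
#' mix; results stay within the positive 32-bit integer range accepted by
#' [set.seed()].
#'
#' @param seed Integer master seed.
#' @param ... Character or integer labels naming the substream
#'   (e.g. `"trial_eeg"`, participant index, trial index).
#' @return A single integer seed.
#' @export
#' @examples
#' sub_seed(1, "pool") != sub_seed(1, "design")
sub_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 216613626L
  for (b in bytes) {
    # FNV-style multiply-xor; the product stays below 2^53 so the double
    # arithmetic is exact
    h <- (bitwXor(h, b) * 16777619) %% 2147483629
    h <- as.integer(h)
  }
  as.integer(h %% 2147483587L) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
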