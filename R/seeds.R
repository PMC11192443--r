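#' Derive a per-stream seed from a master seed and a stream label
#'
#' Expands one user-supplied master seed into independent integer seeds for
#' named random streams (shared signal, participant noise, participation,
#' text, ...). Each stream is identified by a character label; the derived
#' seed is a deterministic hash of the master seed and the label, kept below
#' 2^31 so it is always a valid R integer seed. This makes every module
#' reproducible on its own, independent of the order in which streams are
#' consumed.
#'
#' @param seed integer master seed.
#' @param ... character or numeric labels identifying the stream, e.g.
#'   `stream_seed(1, "noise", "Story", "IFG", "p07")`.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
stream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "\x1f")
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  if (nzchar(labels)) {
    for (code in utf8ToInt(labels)) {
      h <- (h * 131 + code) %% m
    }
  }
  # one multiplicative scramble so seed 0 with empty label is not fixed at 0
  as.integer((h * 48271 + 11) %% m)
}
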