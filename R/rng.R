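#' Derive a stage-labelled child seed from a root seed
#'
#' Every stochastic stage (site placement, pool sizes, allele-frequency
#' noise, permutation tests, ...) seeds its own RNG stream with
#' \code{stageSeed(rootSeed, label)} so that a stage can be rerun in
#' isolation and still reproduce the exact output of a full pipeline run.
#' The mapping is a small deterministic hash of the label mixed with the
#' root seed; results stay inside the 32-bit integer range R requires.
#'
#' @param seed integer root seed.
#' @param label character stage label, e.g. "sites" or "freqs".
#' @return an integer seed in [1, 2^31 - 2].
#' @examples
#' stageSeed(1L, "sites")
#' stageSeed(1L, "freqs")
#' @export
stageSeed <- function(seed, label) {
  stopifnot(length(seed) == 1, is.finite(seed), length(label) == 1)
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% m
  s <- (abs(as.numeric(seed)) %% m)
  as.integer(((s * 69621 + h) %% (m - 1)) + 1)
}
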