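#' Derive a stage seed from a global seed
#'
#' Mixes a global integer seed with one or more integer tags (timepoint,
#' replicate, stage number, ...) into a new seed below 2^31, so that every
#' stage of a run can be re-generated in isolation while the whole run stays
#' a pure function of the single global seed.
#'
#' @param seed global integer seed.
#' @param ... integer tags identifying the stage.
#' @return an integer seed in [0, 2^31 - 1).
#' @export
mix_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- abs(as.double(seed)) %% 2147483647
  for (tag in as.double(c(...))) {
    # 69069: classic LCG multiplier; all arithmetic stays below 2^53
    s <- (s * 69069 + abs(tag) + 1) %% 2147483647
  }
  as.integer(s)
}

# Polynomial rolling hash, used only for provenance stamps in run logs.
hash_string <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
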