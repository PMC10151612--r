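# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

#' Derive a named substream seed from a root seed
#'
#' All randomness in the survey pipelines flows from a single root seed via
#' named substreams, so that any (seed, stage, index) record can be re-run
#' in isolation. The derived seed is a deterministic 31-bit hash.
#'
#' @param root integer root seed.
#' @param name substream name.
#' @param index optional integer distinguishing repeats within a stream.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(root, name, index = 0L) {
  h <- as.double(root %% 2147483647L)
  for (ch in utf8ToInt(paste0(name, ":", index)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}
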