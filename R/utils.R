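#' @importFrom Rcpp sourceCpp
#' @importFrom rlang %||% .data
#' @useDynLib mtqsar, .registration = TRUE
NULL

# run code under a given seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a reproducible 31-bit sub-seed from a parent seed, so one global
# seed fans out to independent substreams per sampling step
.substream <- function(seed, step) {
  (as.numeric(seed) * 48271 + as.numeric(step) * 16807) %% 2147483647
}
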