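#' Derive a stage sub-seed from a global seed
#'
#' One integer seed drives the whole pipeline; each randomised stage draws
#' from a sub-seed derived by hashing the stage name into the global seed.
#' Adding a new stage therefore never perturbs the streams of existing ones.
#'
#' @param seed integer global seed.
#' @param stage character stage name (e.g. `"bathymetry"`, `"mosaic"`).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
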