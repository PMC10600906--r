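# Shared constants and RNG hygiene, loaded before the other source files.

#' @useDynLib sixmApred, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rbinom runif setNames
#' @importFrom utils write.csv read.csv
#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

# Evaluate expr under a seeded RNG stream, then restore the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
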