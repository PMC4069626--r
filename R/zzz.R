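#' @useDynLib pairomega, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dgamma optim optimize pgamma rbinom runif
#' @importFrom utils read.table write.table
NULL

# package-level memo cache (genetic code, pair structure, NG tables)
.pkg_cache <- new.env(parent = emptyenv())

# evaluate `expr` under a temporary RNG seed, restoring global RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
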