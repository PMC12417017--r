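#' @useDynLib sleepstager, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx fft median quantile sd var rnorm runif rbinom
#'   rnbinom predict wilcox.test spline setNames aggregate
#' @importFrom utils head tail read.csv write.csv
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream.  All exported stochastic operations funnel through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-participant seed derivation from a master seed.
# Kept below 2^31 - 1 so the result is always a valid R integer seed.
derive_seed <- function(master_seed, counter) {
  as.integer((as.double(master_seed) * 10007 + 7919 * as.double(counter)) %%
               2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
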