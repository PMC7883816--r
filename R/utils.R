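#' @useDynLib dysreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef complete.cases dexp median pbinom pchisq pnorm pt
#'   p.adjust predict quantile rbinom rexp rnorm runif sd setNames uniroot var
#'   wilcox.test rmultinom
#' @importFrom utils read.delim write.table head
NULL

# Derive a reproducible child seed from a global seed and a string key.
# Keeps per-target / per-repetition randomness independent of execution order.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dysreg <- function(...) stop(..., call. = FALSE)
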