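#' @useDynLib ipvgsem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rbinom runif qlogis plogis qnorm pnorm pchisq
#'   uniroot optim glm quasibinomial coef as.formula aggregate sd setNames
#'   simulate dnorm
#' @importFrom utils write.csv read.csv
NULL

invlogit <- function(x) stats::plogis(x)

logit <- function(p) stats::qlogis(p)

## round half away from zero, as printed survey tables do
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
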