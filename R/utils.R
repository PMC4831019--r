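#' @useDynLib cardiosplice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm median nls pbinom pt qt residuals rnorm rlnorm runif sd setNames t.test var
#' @importFrom utils head tail write.table read.table
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards, so generator calls never perturb each other.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage seed from a global one, kept below 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

boltzmann <- function(v, v_half, slope) 1 / (1 + exp(-(v - v_half) / slope))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}
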