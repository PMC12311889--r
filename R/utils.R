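#' @importFrom methods new validObject is slot
#' @importFrom stats runif rnorm kmeans prcomp dist sd
#' @importFrom grDevices col2rgb hcl.colors
NULL

## Round half away from zero. base::round() rounds half to even, which would
## make bin assignment platform-looking but tie-dependent; one fixed rule
## keeps binning deterministic.
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG stream afterwards so library calls never perturb user code.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Derive a child seed from a master seed; keeps all seeds below 2^31.
deriveSeed <- function(seed, index) {
  (as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647
}

isCount <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x > 0 && x == floor(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
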