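#' @import methods
#' @importFrom stats cor lm optim nlminb pchisq pnorm pt qnorm rnorm
#'   complete.cases setNames runif var sd coef residuals AIC qchisq
#'   uniroot cov
#' @importFrom utils read.csv write.csv packageVersion head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## round-half-up (base round() is banker's rounding, which would bias
## attenuation checks on .5 ties)
roundHalfUp <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## fill a k x k lower-triangular matrix from a vector in row-major order:
## (1,1), (2,1), (2,2), (3,1), (3,2), (3,3), ...
lowerTriFromVec <- function(v, k) {
  m <- matrix(0, k, k)
  idx <- which(lower.tri(m, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  stopifnot(length(v) == nrow(idx))
  m[idx] <- v
  m
}

## lower Cholesky factor (chol() returns the upper factor)
lowerChol <- function(m) t(chol(m))

## canonical per-twin column name, e.g. "wb1_t1"
twinCol <- function(var, twin) paste0(var, "_t", twin)

## stable hash of a config list for artifact provenance (md5 of its
## canonical JSON serialisation)
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

## derive a per-replicate seed from a master seed, kept within 32-bit range
deriveSeed <- function(master, i) {
  as.integer((as.double(master) + 7919 * as.double(i)) %% 2147483587 + 1)
}
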