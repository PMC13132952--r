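## Central S4 classes. Twin-pair data are stored wide, one row per pair,
## with per-twin per-wave measure columns named "<measure><wave>_t<twin>"
## (e.g. wb2_t1 = twin 1's wellbeing at wave 2).

TWIN_MEASURES <- c("wb", "negdep", "negind", "posdep")
TWIN_WAVES <- 1:3

## hard score ranges: Cantril ladder 1-10; life-event counts bounded by
## the number of items in each category (14 negative dependent,
## 19 negative independent, 5 positive dependent)
MEASURE_BOUNDS <- list(
  wb     = c(1, 10),
  negdep = c(0, 14),
  negind = c(0, 19),
  posdep = c(0, 5)
)

measureWaveCols <- function(measures = TWIN_MEASURES, waves = TWIN_WAVES) {
  as.vector(t(outer(measures, waves, paste0)))
}

#' TwinDataset: wide twin-pair data
#'
#' One row per twin pair with a family identifier, zygosity (\code{"MZ"} or
#' \code{"DZ"}) and per-twin, per-wave measure columns named
#' \code{"<measure><wave>_t<twin>"}. Recognised measures are \code{wb}
#' (Cantril-ladder wellbeing, 1-10), \code{negdep} (negative dependent
#' life-event count, 0-14), \code{negind} (negative independent, 0-19),
#' \code{posdep} (positive dependent, 0-5), plus optional \code{age<w>_t<t>}
#' and \code{sex_t<t>}.
#'
#' @slot pairs data.frame, one row per twin pair.
#' @slot variables character, per-twin measure-wave columns present
#'   (without the \code{_t<twin>} suffix).
#' @export
setClass("TwinDataset",
  representation(pairs = "data.frame", variables = "character"))

setValidity("TwinDataset", function(object) {
  p <- object@pairs
  msgs <- character()
  if (!all(c("family_id", "zygosity") %in% names(p)))
    msgs <- c(msgs, "pairs must have 'family_id' and 'zygosity' columns")
  else {
    if (anyDuplicated(p$family_id))
      msgs <- c(msgs, "family_id must be unique per pair record")
    if (any(is.na(p$zygosity)) || !all(p$zygosity %in% c("MZ", "DZ")))
      msgs <- c(msgs, "zygosity must be 'MZ' or 'DZ' for every record")
  }
  for (v in object@variables) {
    if (!all(twinCol(v, 1:2) %in% names(p)))
      msgs <- c(msgs, sprintf("missing columns for variable '%s'", v))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TwinDataset from a wide pair table
#'
#' @param pairs data.frame with \code{family_id}, \code{zygosity} and
#'   per-twin measure columns.
#' @return A \linkS4class{TwinDataset}.
#' @export
TwinDataset <- function(pairs) {
  pairs <- as.data.frame(pairs)
  cand <- measureWaveCols()
  vars <- cand[vapply(cand, function(v)
    all(twinCol(v, 1:2) %in% names(pairs)), logical(1))]
  new("TwinDataset", pairs = pairs, variables = vars)
}

#' @describeIn TwinDataset-class number of twin pairs
#' @param object,x a TwinDataset
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname TwinDataset-class
#' @export
setMethod("nPairs", "TwinDataset", function(x) nrow(x@pairs))

#' Pair-level data of a TwinDataset
#' @param x a TwinDataset
#' @return the underlying data.frame (one row per pair)
#' @export
pairData <- function(x) {
  stopifnot(is(x, "TwinDataset"))
  x@pairs
}

#' Zygosity vector of a TwinDataset
#' @param x a TwinDataset
#' @export
zygosity <- function(x) {
  stopifnot(is(x, "TwinDataset"))
  x@pairs$zygosity
}

setMethod("show", "TwinDataset", function(object) {
  z <- table(factor(object@pairs$zygosity, c("MZ", "DZ")))
  cat(sprintf("TwinDataset: %d pairs (%d MZ, %d DZ)\n",
              nrow(object@pairs), z[["MZ"]], z[["DZ"]]))
  cat("  variables:", paste(object@variables, collapse = ", "), "\n")
})

#' SourceLoadingModel: a twin structural model as loadings on independent
#' standard-normal sources
#'
#' A model is defined per twin by component loading matrices
#' \eqn{\Lambda_A, \Lambda_C, \Lambda_E} (functions of the parameter vector)
#' and a mean vector. The pair-level implied covariance follows from the
#' biometric sharing rules: A sources correlate 1 (MZ) / 0.5 (DZ) across
#' co-twins, C sources are fully shared, E sources are twin-specific.
#'
#' @slot name model identifier.
#' @slot variables per-twin observed variable names, in model order.
#' @slot paramNames,lower,upper free-parameter names and box bounds.
#' @slot loadings function(theta) -> named list of per-twin loading
#'   matrices (subset of A, C, E), rows in \code{variables} order.
#' @slot means function(theta) -> per-twin mean vector.
#' @slot startFun function(ds) -> data-driven starting values.
#' @slot meta list of model-specific metadata (configs, trait labels).
#' @export
setClass("SourceLoadingModel",
  representation(name = "character", variables = "character",
                 paramNames = "character", lower = "numeric",
                 upper = "numeric", loadings = "function",
                 means = "function", startFun = "function", meta = "list"))

setValidity("SourceLoadingModel", function(object) {
  q <- length(object@paramNames)
  if (length(object@lower) != q || length(object@upper) != q)
    return("bounds must match parameter vector length")
  TRUE
})

#' @describeIn SourceLoadingModel-class number of free parameters
#' @param x a SourceLoadingModel
#' @export
setGeneric("nParams", function(x) standardGeneric("nParams"))

#' @rdname SourceLoadingModel-class
#' @export
setMethod("nParams", "SourceLoadingModel",
          function(x) length(x@paramNames))

setMethod("show", "SourceLoadingModel", function(object) {
  cat(sprintf("SourceLoadingModel '%s': %d observed per twin, %d free parameters\n",
              object@name, length(object@variables),
              length(object@paramNames)))
})

#' FitResult: a fitted twin structural model
#'
#' @slot model the fitted \linkS4class{SourceLoadingModel}.
#' @slot theta named estimate vector.
#' @slot minus2LL -2 log-likelihood at the optimum.
#' @slot converged logical convergence status of the best start.
#' @slot gradNorm max-norm of the numerical gradient of -2lnL at the
#'   optimum (NA if not computed).
#' @slot nPairs named per-group pair counts (MZ, DZ).
#' @slot se named standard errors (delta of the numerical Hessian;
#'   length 0 until \code{standardErrors()} is called).
#' @slot vcov parameter covariance matrix (0 x 0 until computed).
#' @slot seReliable logical; FALSE when the Hessian was not positive
#'   definite.
#' @slot details per-start optimizer diagnostics.
#' @export
setClass("FitResult",
  representation(model = "SourceLoadingModel", theta = "numeric",
                 minus2LL = "numeric", converged = "logical",
                 gradNorm = "numeric", nPairs = "numeric", se = "numeric",
                 vcov = "matrix", seReliable = "logical", details = "list"))

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult '%s': -2lnL = %.4f, q = %d, converged = %s\n",
              object@model@name, object@minus2LL, length(object@theta),
              object@converged))
  cat(sprintf("  pairs: %d MZ, %d DZ\n",
              object@nPairs[["MZ"]], object@nPairs[["DZ"]]))
})

#' Coefficients of a fitted twin model
#' @param object a FitResult
#' @param ... ignored
#' @export
setMethod("coef", "FitResult", function(object, ...) object@theta)

#' -2 log-likelihood of a fit
#' @param x a FitResult
#' @export
minus2LL <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@minus2LL
}

#' AIC of a fitted twin model (-2lnL + 2q)
#' @param object a FitResult
#' @param ...,k ignored (the twin-model convention k = 2 is always used)
#' @export
setMethod("AIC", "FitResult", function(object, ..., k = 2)
  object@minus2LL + 2 * length(object@theta))

#' FitIndices: likelihood-based fit statistics
#'
#' @slot chisq,df,p likelihood-ratio chi-square against the saturated
#'   model, its degrees of freedom, and p-value.
#' @slot cfi,tli,rmsea incremental/absolute fit indices (NA when
#'   undefined, e.g. df = 0 for RMSEA/TLI).
#' @slot aic Akaike's information criterion of the target model.
#' @slot meta conventions used (multi-group RMSEA factor, group count).
#' @export
setClass("FitIndices",
  representation(chisq = "numeric", df = "numeric", p = "numeric",
                 cfi = "numeric", tli = "numeric", rmsea = "numeric",
                 aic = "numeric", meta = "list"))

setMethod("show", "FitIndices", function(object) {
  cat(sprintf("chisq(%d) = %.3f, p = %.4f | CFI = %.3f, TLI = %.3f, RMSEA = %.4f, AIC = %.2f\n",
              object@df, object@chisq, object@p, object@cfi, object@tli,
              object@rmsea, object@aic))
})

#' CholeskyParams: trivariate Cholesky ACE/AE parameters
#'
#' @slot a,c,e lower-triangular 3x3 path matrices (c is all-zero in the
#'   AE configuration).
#' @slot mu the 3 means.
#' @slot config "ACE" or "AE".
#' @export
setClass("CholeskyParams",
  representation(a = "matrix", c = "matrix", e = "matrix", mu = "numeric",
                 config = "character"))

setValidity("CholeskyParams", function(object) {
  ok <- function(m) all(m[upper.tri(m)] == 0)
  if (!ok(object@a) || !ok(object@c) || !ok(object@e))
    return("path matrices must be lower triangular")
  if (length(object@mu) != nrow(object@a))
    return("means must match the number of waves")
  TRUE
})

#' RiclpmParams: genetically informative RI-CLPM parameters
#'
#' Structured view of the bivariate three-wave model: per-component 2x2
#' lower-Cholesky blocks for the random intercepts (\code{ri}), the wave-1
#' within-person factors (\code{w1}) and the wave-2/3 innovations
#' (\code{i2}, \code{i3}); the 2x2 lagged-path matrices \code{T1}
#' (wave 1 to 2) and \code{T2} (wave 2 to 3) in the order (x, y); and the 6
#' means. \code{config} records which of A, C, E each trait includes.
#' @slot ri,w1,i2,i3 named lists of 2x2 lower-triangular matrices, one per
#'   included component.
#' @slot T1,T2 lagged-path matrices \code{rbind(c(b_x, g_xy), c(g_yx, b_y))}.
#' @slot mu means of (x1, y1, x2, y2, x3, y3).
#' @slot config list(x = components, y = components).
#' @export
setClass("RiclpmParams",
  representation(ri = "list", w1 = "list", i2 = "list", i3 = "list",
                 T1 = "matrix", T2 = "matrix", mu = "numeric",
                 config = "list"))
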