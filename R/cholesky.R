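## Trivariate Cholesky ACE/AE decomposition of a three-wave phenotype.

CHOL_TRI_NAMES <- c("11", "21", "22", "31", "32", "33")

#' Build a trivariate Cholesky twin model
#'
#' Lower-triangular path matrices per component map three independent
#' standard-normal sources per included component to the three phenotype
#' waves; diagonal paths are bounded at zero to fix the Cholesky sign
#' indeterminacy. Free parameters: 6 per included triangle plus 3 means
#' (AE: 15, ACE: 21).
#'
#' @param config \code{"AE"} or \code{"ACE"}.
#' @param variables the three per-twin phenotype columns, in wave order.
#' @return A \linkS4class{SourceLoadingModel}.
#' @export
buildCholeskyModel <- function(config = c("AE", "ACE"),
                               variables = c("wb1", "wb2", "wb3")) {
  config <- match.arg(config)
  stopifnot(length(variables) == 3)
  comps <- if (config == "ACE") c("a", "c", "e") else c("a", "e")
  pn <- c(unlist(lapply(comps, function(k) paste0(k, CHOL_TRI_NAMES))),
          paste0("mu", 1:3))
  diagIdx <- grep("(11|22|33)$", pn[seq_len(6 * length(comps))])
  lower <- rep(-Inf, length(pn))
  lower[diagIdx] <- 0
  upper <- rep(Inf, length(pn))
  loadings <- function(theta) {
    theta <- as.numeric(theta)
    out <- list()
    for (i in seq_along(comps))
      out[[toupper(comps[i])]] <-
        lowerTriFromVec(theta[(i - 1) * 6 + 1:6], 3)
    out
  }
  means <- function(theta) as.numeric(theta)[6 * length(comps) + 1:3]
  startFun <- function(ds) {
    ind <- individualTable(ds, variables)
    v <- vapply(variables, function(x) var(ind[[x]], na.rm = TRUE), 0)
    m <- vapply(variables, function(x) mean(ind[[x]], na.rm = TRUE), 0)
    k <- length(comps)
    st <- setNames(numeric(length(pn)), pn)
    for (cc in comps)
      st[paste0(cc, c("11", "22", "33"))] <- sqrt(v / k)
    st[paste0("mu", 1:3)] <- m
    st
  }
  new("SourceLoadingModel", name = paste0("cholesky_", config),
      variables = variables, paramNames = pn, lower = lower,
      upper = upper, loadings = loadings, means = means,
      startFun = startFun,
      meta = list(kind = "cholesky", config = config))
}

#' Structured view of Cholesky parameters
#'
#' @param model a Cholesky SourceLoadingModel.
#' @param theta parameter vector in model order.
#' @return A \linkS4class{CholeskyParams}.
#' @export
choleskyParams <- function(model, theta) {
  stopifnot(model@meta$kind == "cholesky")
  lam <- model@loadings(theta)
  new("CholeskyParams", a = lam$A,
      c = lam$C %||% matrix(0, 3, 3), e = lam$E,
      mu = model@means(theta), config = model@meta$config)
}

shareFun <- function(model, which, wave) {
  force(which); force(wave)
  function(theta) {
    lam <- model@loadings(theta)
    tot <- 0
    for (k in names(lam)) tot <- tot + tcrossprod(lam[[k]])[wave, wave]
    comp <- if (which %in% names(lam))
      tcrossprod(lam[[which]])[wave, wave] else 0
    comp / tot
  }
}

#' Standardized variance components of a Cholesky fit
#'
#' Per wave, the standardized shares \eqn{a^2 = (aa')_{ww}/\Sigma_{ww}}
#' (heritability), \eqn{c^2}, \eqn{e^2}; shares sum to one by
#' construction. Confidence intervals by the delta method when a
#' parameter covariance matrix is available (from
#' \code{\link{standardErrors}}).
#'
#' @param fit a FitResult from a Cholesky model (or a model plus theta via
#'   \code{model}/\code{theta}).
#' @param ciLevel confidence level for the delta-method intervals.
#' @return data.frame with one row per wave: \code{a2}, \code{c2},
#'   \code{e2}, and CI bounds when available.
#' @export
standardizedComponents <- function(fit, ciLevel = 0.95) {
  model <- fit@model
  stopifnot(model@meta$kind == "cholesky")
  theta <- as.numeric(fit@theta)
  comps <- if (model@meta$config == "ACE") c("A", "C", "E") else c("A", "E")
  haveV <- nrow(fit@vcov) == length(theta)
  zc <- qnorm(1 - (1 - ciLevel) / 2)
  rows <- lapply(1:3, function(w) {
    row <- list(wave = w)
    for (k in comps) {
      f <- shareFun(model, k, w)
      val <- f(theta)
      nm <- paste0(tolower(k), "2")
      row[[nm]] <- val
      if (haveV) {
        g <- pracma::grad(f, theta)
        se <- sqrt(max(drop(g %*% fit@vcov %*% g), 0))
        row[[paste0(nm, "_lower")]] <- clamp(val - zc * se, 0, 1)
        row[[paste0(nm, "_upper")]] <- clamp(val + zc * se, 0, 1)
        row[[paste0(nm, "_se")]] <- se
      }
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

#' Compare AE and ACE Cholesky configurations by AIC
#'
#' Fits both configurations to the same data and selects the one with the
#' lower AIC; ties (|dAIC| below 1e-6) go to the simpler AE model.
#'
#' @param ds a TwinDataset with the three phenotype waves.
#' @param variables per-twin phenotype columns.
#' @param options optimizer options passed to \code{\link{fitModel}}.
#' @return list: \code{selected} ("AE"/"ACE"), \code{fits} (both
#'   FitResults), \code{aic}, \code{dAIC} (AIC_ACE - AIC_AE).
#' @export
compareAceAe <- function(ds, variables = c("wb1", "wb2", "wb3"),
                         options = list()) {
  fits <- lapply(setNames(nm = c("AE", "ACE")), function(cfg)
    fitModel(buildCholeskyModel(cfg, variables), ds, options))
  if (!all(vapply(fits, function(f) f@converged, TRUE)))
    stop("Cholesky model comparison aborted: non-convergent fit (",
         paste(names(fits)[!vapply(fits, function(f) f@converged, TRUE)],
               collapse = ", "), ")")
  aic <- vapply(fits, AIC, 0)
  dAIC <- aic[["ACE"]] - aic[["AE"]]
  selected <- if (dAIC > -1e-6) "AE" else "ACE"
  list(selected = selected, fits = fits, aic = aic, dAIC = dAIC)
}
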