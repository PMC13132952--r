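## Multi-group Gaussian FIML core: model-implied moments, raw-data
## likelihood under arbitrary missingness, optimization, numerical
## standard errors, reference models and fit indices.

## cross-twin genetic correlation: MZ 1, DZ 0.5
A_SHARE <- c(MZ = 1, DZ = 0.5)

#' Model-implied moments for a zygosity group
#'
#' The pair-level covariance follows from the per-twin component loadings
#' \eqn{\Lambda_k}: within-twin \eqn{\Sigma_W = \sum_k \Lambda_k\Lambda_k'};
#' cross-twin \eqn{\Sigma_X = \bar r\,\Lambda_A\Lambda_A' +
#' \Lambda_C\Lambda_C'} with \eqn{\bar r = 1} (MZ) or 0.5 (DZ). E
#' contributes only within twin. Means are equated across co-twins.
#'
#' @param model a \linkS4class{SourceLoadingModel}.
#' @param theta parameter vector (model order).
#' @param group \code{"MZ"} or \code{"DZ"}.
#' @return list with \code{mu} (length 2p) and \code{sigma} (2p x 2p).
#' @export
expectedMoments <- function(model, theta, group = c("MZ", "DZ")) {
  group <- match.arg(group)
  if (any(!is.finite(theta))) stop("non-finite parameter value")
  lam <- model@loadings(theta)
  p <- length(model@variables)
  within <- matrix(0, p, p)
  cross <- matrix(0, p, p)
  for (k in names(lam)) {
    G <- tcrossprod(lam[[k]])
    within <- within + G
    if (k == "A") cross <- cross + A_SHARE[[group]] * G
    if (k == "C") cross <- cross + G
  }
  sigma <- rbind(cbind(within, cross), cbind(t(cross), within))
  m <- model@means(theta)
  vn <- c(twinCol(model@variables, 1), twinCol(model@variables, 2))
  dimnames(sigma) <- list(vn, vn)
  list(mu = setNames(c(m, m), vn), sigma = sigma)
}

## observed pair-data matrix for a model, one group
pairMatrix <- function(ds, model, group) {
  cols <- c(twinCol(model@variables, 1), twinCol(model@variables, 2))
  miss <- setdiff(cols, names(ds@pairs))
  if (length(miss))
    stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  as.matrix(ds@pairs[ds@pairs$zygosity == group, cols, drop = FALSE])
}

## sufficient statistics per missingness pattern: rows sharing a pattern
## contribute through their count, mean and ML scatter only, which gives
## a likelihood identical to row-by-row evaluation
patternStats <- function(X) {
  obs <- !is.na(X)
  keep <- rowSums(obs) > 0
  X <- X[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  if (!nrow(X)) return(list())
  key <- apply(obs, 1, function(o) paste(which(o), collapse = ","))
  lapply(split(seq_len(nrow(X)), key), function(idx) {
    o <- obs[idx[1], ]
    Xi <- X[idx, o, drop = FALSE]
    n <- nrow(Xi)
    xbar <- colMeans(Xi)
    Xc <- sweep(Xi, 2, xbar)
    list(obs = which(o), n = n, xbar = xbar, S = crossprod(Xc) / n)
  })
}

## -2lnL contribution of one pattern given full-group moments
patternMinus2LL <- function(pat, mu, sigma) {
  o <- pat$obs
  k <- length(o)
  Si <- sigma[o, o, drop = FALSE]
  R <- tryCatch(chol(Si), error = function(e) NULL)
  if (is.null(R)) return(structure(1e10 * pat$n, singular = TRUE))
  logdet <- 2 * sum(log(diag(R)))
  Sinv <- chol2inv(R)
  delta <- pat$xbar - mu[o]
  pat$n * (k * log(2 * pi) + logdet + sum(Sinv * pat$S) +
             drop(delta %*% Sinv %*% delta))
}

statsForModel <- function(ds, model) {
  lapply(setNames(nm = c("MZ", "DZ")),
         function(g) patternStats(pairMatrix(ds, model, g)))
}

minus2LLFromStats <- function(model, theta, stats) {
  total <- 0
  for (g in names(stats)) {
    if (!length(stats[[g]])) next
    mom <- expectedMoments(model, theta, g)
    for (pat in stats[[g]])
      total <- total + patternMinus2LL(pat, mom$mu, mom$sigma)
  }
  as.numeric(total)
}

#' Raw-data FIML -2 log-likelihood
#'
#' Each pair-row contributes the multivariate-normal -2 log density of its
#' observed sub-vector under the group's implied moments; rows with no
#' observed variable are dropped. Rows are grouped by missingness pattern
#' for speed; the result is identical to row-by-row evaluation.
#'
#' @param model a SourceLoadingModel.
#' @param theta parameter vector.
#' @param ds a TwinDataset.
#' @return the scalar -2lnL.
#' @export
fimlMinus2LL <- function(model, theta, ds) {
  minus2LLFromStats(model, theta, statsForModel(ds, model))
}

## reference implementation, one row at a time (contract check)
rowwiseMinus2LL <- function(model, theta, ds) {
  total <- 0
  for (g in c("MZ", "DZ")) {
    X <- pairMatrix(ds, model, g)
    if (!nrow(X)) next
    mom <- expectedMoments(model, theta, g)
    for (i in seq_len(nrow(X))) {
      o <- which(!is.na(X[i, ]))
      if (!length(o)) next
      Si <- mom$sigma[o, o, drop = FALSE]
      d <- X[i, o] - mom$mu[o]
      total <- total + length(o) * log(2 * pi) +
        determinant(Si)$modulus[1] + drop(d %*% solve(Si, d))
    }
  }
  as.numeric(total)
}

#' Fit a twin structural model by FIML
#'
#' Minimizes the raw-data -2lnL with a bounded quasi-Newton optimizer
#' (PORT routines via \code{nlminb}) from multiple jittered starts.
#' Starting values come from the model's data-driven heuristic unless
#' supplied. Cholesky diagonal paths are bounded at zero, which fixes the
#' sign indeterminacy of the parameterization without restricting the
#' implied covariance.
#'
#' @param model a SourceLoadingModel.
#' @param ds a TwinDataset.
#' @param options list: \code{nStarts} (default 5), \code{jitterSd}
#'   (default 0.2), \code{seed} (jitter seed, default 1), \code{start}
#'   (explicit start vector), \code{relTol} (convergence tolerance on the
#'   objective, default 1e-8), \code{maxIter}, \code{gradCheck} (compute
#'   the gradient norm at the optimum, default TRUE).
#' @return A \linkS4class{FitResult}.
#' @export
fitModel <- function(model, ds, options = list()) {
  o <- modifyList(list(nStarts = 5, jitterSd = 0.2, seed = 1, start = NULL,
                       relTol = 1e-8, maxIter = 1000, gradCheck = TRUE),
                  options)
  stats <- statsForModel(ds, model)
  nmz <- sum(vapply(stats$MZ, `[[`, 0, "n"))
  ndz <- sum(vapply(stats$DZ, `[[`, 0, "n"))
  obj <- function(th) {
    v <- minus2LLFromStats(model, th, stats)
    if (!is.finite(v)) 1e12 else v
  }
  start0 <- o$start %||% model@startFun(ds)
  q <- nParams(model)
  stopifnot(length(start0) == q)
  starts <- list(clamp(start0, model@lower, model@upper))
  if (o$nStarts > 1) {
    rng <- withr_seed(o$seed)
    on.exit(rng(), add = TRUE)
    scale <- pmax(abs(start0), 0.25)
    for (i in seq_len(o$nStarts - 1))
      starts[[i + 1]] <- clamp(start0 + rnorm(q, 0, o$jitterSd * scale),
                               model@lower, model@upper)
  }
  runs <- lapply(starts, function(st) {
    tryCatch(
      nlminb(st, obj, lower = model@lower, upper = model@upper,
             control = list(iter.max = o$maxIter, eval.max = 4 * o$maxIter,
                            rel.tol = o$relTol)),
      error = function(e) list(objective = Inf, convergence = 1L,
                               message = conditionMessage(e), par = st))
  })
  objs <- vapply(runs, function(r) r$objective, 0)
  if (all(!is.finite(objs)))
    stop("all optimizer starts failed: ",
         paste(vapply(runs, function(r) r$message %||% "?", ""),
               collapse = "; "))
  best <- runs[[which.min(objs)]]
  theta <- setNames(best$par, model@paramNames)
  gn <- NA_real_
  if (isTRUE(o$gradCheck)) {
    gn <- max(abs(pracma::grad(obj, as.numeric(theta))))
    ## relative check: interior gradient should vanish up to scaling by
    ## the objective's magnitude (boundary parameters excepted)
    if (gn > 1e-4 * max(1, abs(best$objective)) &&
        all(theta > model@lower + 1e-8))
      warning(sprintf("gradient norm %.3g at optimum; solution may be inexact", gn))
  }
  new("FitResult", model = model, theta = theta,
      minus2LL = best$objective,
      converged = identical(best$convergence, 0L) && is.finite(best$objective),
      gradNorm = gn, nPairs = c(MZ = nmz, DZ = ndz),
      se = numeric(0), vcov = matrix(0, 0, 0), seReliable = NA,
      details = list(starts = length(starts),
                     objectives = objs,
                     messages = vapply(runs, function(r)
                       r$message %||% "", "")))
}

## localized seed handling: restore the caller's RNG state afterwards
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Standard errors from the numerical Hessian
#'
#' Computes the observed-information standard errors as the square roots
#' of the diagonal of the inverse Hessian of \eqn{\tfrac12(-2\ln L)} at
#' the optimum (central finite differences). A non-positive-definite
#' Hessian flags the SEs as unreliable; an inversion failure leaves them
#' missing while the fit is retained.
#'
#' @param fit a converged FitResult.
#' @param ds the dataset the model was fitted to.
#' @return the FitResult with \code{se}, \code{vcov} and
#'   \code{seReliable} filled in.
#' @export
standardErrors <- function(fit, ds) {
  stats <- statsForModel(ds, fit@model)
  f <- function(th) 0.5 * minus2LLFromStats(fit@model, th, stats)
  H <- pracma::hessian(f, as.numeric(fit@theta))
  H <- (H + t(H)) / 2
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) {
    fit@se <- setNames(rep(NA_real_, length(fit@theta)),
                       names(fit@theta))
    fit@seReliable <- FALSE
    return(fit)
  }
  d <- diag(V)
  reliable <- all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 0)
  fit@se <- setNames(sqrt(pmax(d, 0)), names(fit@theta))
  if (any(d <= 0)) fit@se[d <= 0] <- NA_real_
  fit@vcov <- V
  fit@seReliable <- reliable
  fit
}

## placeholder model carrying only a name, variable list and q (used by
## the saturated/independence reference fits)
referenceModelStub <- function(name, variables, paramNames) {
  new("SourceLoadingModel", name = name, variables = variables,
      paramNames = paramNames,
      lower = rep(-Inf, length(paramNames)),
      upper = rep(Inf, length(paramNames)),
      loadings = function(theta) stop("reference model has no loadings"),
      means = function(theta) stop("reference model has no means"),
      startFun = function(ds) stop("reference model has no start"),
      meta = list(reference = TRUE))
}

## complete-data closed-form -2lnL at the saturated MLE
saturatedClosedForm <- function(X) {
  n <- nrow(X); k <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / n
  list(m2ll = n * (k * log(2 * pi) + determinant(S)$modulus[1] + k),
       mu = mu, sigma = S)
}

#' Saturated reference model under FIML
#'
#' Free mean vector and free covariance matrix per zygosity group. With
#' complete data the maximum is available in closed form at the sample
#' moments (ML divisor n); with missingness the group likelihood is
#' maximized numerically over the means and the lower-Cholesky factor of
#' the covariance.
#'
#' @param ds a TwinDataset.
#' @param variables per-twin variable names defining the observed vector.
#' @return A FitResult (theta holds per-group means and covariance
#'   Cholesky entries).
#' @export
fitSaturated <- function(ds, variables) {
  total <- 0
  theta <- numeric(0)
  nmz <- ndz <- 0
  conv <- TRUE
  for (g in c("MZ", "DZ")) {
    X <- pairMatrix(ds, referenceModelStub("x", variables, character(0)), g)
    X <- X[rowSums(!is.na(X)) > 0, , drop = FALSE]
    if (g == "MZ") nmz <- nrow(X) else ndz <- nrow(X)
    if (!nrow(X)) next
    k <- ncol(X)
    if (!anyNA(X)) {
      cf <- saturatedClosedForm(X)
      total <- total + cf$m2ll
      L <- lowerChol(cf$sigma + diag(1e-10, k))
      theta <- c(theta, setNames(
        c(cf$mu, L[lower.tri(L, diag = TRUE)]),
        paste0(g, "_", c(paste0("mu", seq_len(k)),
                         paste0("l", seq_len(k * (k + 1) / 2))))))
    } else {
      pats <- patternStats(X)
      nltri <- k * (k + 1) / 2
      unpack <- function(th) {
        mu <- th[seq_len(k)]
        L <- matrix(0, k, k)
        L[lower.tri(L, diag = TRUE)] <- th[k + seq_len(nltri)]
        list(mu = mu, sigma = tcrossprod(L))
      }
      objg <- function(th) {
        m <- unpack(th)
        v <- sum(vapply(pats, patternMinus2LL, 0, mu = m$mu,
                        sigma = m$sigma))
        if (!is.finite(v)) 1e12 else v
      }
      mu0 <- colMeans(X, na.rm = TRUE)
      mu0[!is.finite(mu0)] <- 0
      S0 <- stats::cov(X, use = "pairwise.complete.obs")
      S0[!is.finite(S0)] <- 0
      diag(S0)[diag(S0) <= 0] <- 1
      ev <- eigen(S0, symmetric = TRUE)
      S0 <- ev$vectors %*% diag(pmax(ev$values, 0.05), k) %*% t(ev$vectors)
      L0 <- lowerChol(S0)
      st <- c(mu0, L0[lower.tri(L0, diag = TRUE)])
      lo <- rep(-Inf, length(st))
      diagIdx <- k + which(lower.tri(diag(k), diag = TRUE) & diag(k) == 1)
      ## keep Cholesky diagonals positive for identification
      ltri <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
      lo[k + which(ltri[, 1] == ltri[, 2])] <- 1e-8
      run <- nlminb(st, objg, lower = lo,
                    control = list(iter.max = 2000, eval.max = 8000,
                                   rel.tol = 1e-10))
      conv <- conv && run$convergence == 0L
      total <- total + run$objective
      theta <- c(theta, setNames(run$par,
        paste0(g, "_", c(paste0("mu", seq_len(k)),
                         paste0("l", seq_len(nltri))))))
    }
  }
  new("FitResult",
      model = referenceModelStub("saturated", variables, names(theta)),
      theta = theta, minus2LL = total, converged = conv,
      gradNorm = NA_real_, nPairs = c(MZ = nmz, DZ = ndz),
      se = numeric(0), vcov = matrix(0, 0, 0), seReliable = NA,
      details = list())
}

#' Independence reference model under FIML
#'
#' Free means and a diagonal covariance per group. Because the likelihood
#' factorizes over variables, the FIML maximum is available in closed form
#' from each variable's observed values (ML variance divisor n).
#'
#' @inheritParams fitSaturated
#' @return A FitResult.
#' @export
fitIndependence <- function(ds, variables) {
  total <- 0
  theta <- numeric(0)
  nmz <- ndz <- 0
  for (g in c("MZ", "DZ")) {
    X <- pairMatrix(ds, referenceModelStub("x", variables, character(0)), g)
    X <- X[rowSums(!is.na(X)) > 0, , drop = FALSE]
    if (g == "MZ") nmz <- nrow(X) else ndz <- nrow(X)
    if (!nrow(X)) next
    for (j in seq_len(ncol(X))) {
      v <- X[!is.na(X[, j]), j]
      if (!length(v)) { theta <- c(theta, setNames(c(NA, NA),
        paste0(g, "_", c("mu", "var"), j))); next }
      mu <- mean(v)
      s2 <- mean((v - mu)^2)
      total <- total + length(v) * (log(2 * pi) + log(s2) + 1)
      theta <- c(theta, setNames(c(mu, s2),
                                 paste0(g, "_", c("mu", "var"), j)))
    }
  }
  new("FitResult",
      model = referenceModelStub("independence", variables, names(theta)),
      theta = theta, minus2LL = total, converged = TRUE,
      gradNorm = NA_real_, nPairs = c(MZ = nmz, DZ = ndz),
      se = numeric(0), vcov = matrix(0, 0, 0), seReliable = NA,
      details = list())
}

#' Likelihood-based fit indices
#'
#' Chi-square against the saturated model, CFI/TLI against the
#' independence model, RMSEA with the multi-group convention that places
#' the number of groups G under the root
#' (\eqn{\sqrt{G\,\max(T-df,0)/(df\,(N-G))}}; conventions placing G
#' elsewhere differ by \eqn{\sqrt G}), and AIC.
#'
#' @param target,saturated,independence FitResults on the identical
#'   dataset.
#' @param nTotal total number of pair rows (default: taken from the
#'   target fit).
#' @return A \linkS4class{FitIndices}.
#' @export
fitIndices <- function(target, saturated, independence, nTotal = NULL) {
  G <- 2
  nTotal <- nTotal %||% sum(target@nPairs)
  q <- function(f) length(f@theta)
  T1 <- max(target@minus2LL - saturated@minus2LL, 0)
  df1 <- q(saturated) - q(target)
  T0 <- max(independence@minus2LL - saturated@minus2LL, 0)
  df0 <- q(saturated) - q(independence)
  if (df1 < 0) stop("target model has more parameters than the saturated model")
  p <- if (df1 > 0) pchisq(T1, df1, lower.tail = FALSE) else NA_real_
  cfi <- 1 - max(T1 - df1, 0) / max(T0 - df0, T1 - df1, 0)
  cfi <- clamp(cfi, 0, 1)
  if (df1 > 0 && df0 > 0 && (T0 / df0) > 1) {
    tli <- clamp(((T0 / df0) - (T1 / df1)) / ((T0 / df0) - 1), 0, 1)
  } else tli <- NA_real_
  rmsea <- if (df1 > 0)
    sqrt(G * max(T1 - df1, 0) / (df1 * (nTotal - G))) else NA_real_
  new("FitIndices", chisq = T1, df = df1, p = p, cfi = cfi, tli = tli,
      rmsea = rmsea, aic = target@minus2LL + 2 * q(target),
      meta = list(groups = G, rmseaConvention = "G under the root",
                  nTotal = nTotal))
}

#' Profile-likelihood confidence interval for one parameter
#'
#' Bisection on the likelihood-ratio boundary: the interval contains the
#' values v of the chosen parameter for which refitting all remaining
#' parameters leaves -2lnL within \code{qchisq(level, 1)} of the optimum
#' (3.84 at the default level).
#'
#' @param fit a converged FitResult.
#' @param ds the dataset used for the fit.
#' @param param parameter name.
#' @param level confidence level.
#' @param maxStep search range in units of \code{step} (an initial guess
#'   of the parameter's scale; default from the curvature-free heuristic
#'   |theta| / 4 + 0.1).
#' @return numeric c(lower, upper); a bound is NA when the likelihood
#'   stays flat over the searched range.
#' @export
profileCI <- function(fit, ds, param, level = 0.95, maxStep = 20) {
  j <- match(param, names(fit@theta))
  if (is.na(j)) stop("unknown parameter: ", param)
  model <- fit@model
  stats <- statsForModel(ds, model)
  th0 <- as.numeric(fit@theta)
  crit <- fit@minus2LL + qchisq(level, 1)
  prof <- function(v) {
    obj <- function(rest) {
      th <- th0
      th[-j] <- rest
      th[j] <- v
      w <- minus2LLFromStats(model, th, stats)
      if (!is.finite(w)) 1e12 else w
    }
    nlminb(th0[-j], obj, lower = model@lower[-j], upper = model@upper[-j],
           control = list(iter.max = 500, rel.tol = 1e-9))$objective
  }
  step <- abs(th0[j]) / 4 + 0.1
  bound <- function(dir) {
    lo <- th0[j]
    for (i in seq_len(maxStep)) {
      hi <- th0[j] + dir * i * step
      if (dir < 0 && hi < model@lower[j]) hi <- model@lower[j]
      if (dir > 0 && hi > model@upper[j]) hi <- model@upper[j]
      if (prof(hi) >= crit)
        return(uniroot(function(v) prof(v) - crit, sort(c(lo, hi)),
                       tol = 1e-4)$root)
      lo <- hi
      if (hi %in% c(model@lower[j], model@upper[j])) return(hi)
    }
    NA_real_
  }
  c(lower = bound(-1), upper = bound(1))
}

#' Likelihood-ratio test between nested fits
#'
#' @param full,nested FitResults on the same dataset, nested q < full q.
#' @return list with \code{chisq} (clamped at 0), \code{df}, \code{p}.
#' @export
likelihoodRatioTest <- function(full, nested) {
  qf <- length(full@theta); qn <- length(nested@theta)
  if (qn >= qf) stop("nested model must have fewer free parameters")
  d <- nested@minus2LL - full@minus2LL
  if (d < -1e-6)
    warning("nested model fits better than the full model; optimizer failure suspected")
  d <- max(d, 0)
  df <- qf - qn
  list(chisq = d, df = df, p = pchisq(d, df, lower.tail = FALSE))
}
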