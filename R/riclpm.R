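## Genetically informative bivariate three-wave RI-CLPM.
##
## Per twin, the observed 6-vector (x1, y1, x2, y2, x3, y3) is
##   obs = mu + RI + w,   w1 = s1, w2 = T1 s1 + s2, w3 = T2 T1 s1 + T2 s2 + s3
## where the random intercepts RI and the wave sources s_w are each
## decomposed into biometric components through 2x2 lower-Cholesky blocks
## (a single variance when one trait excludes a component), and the
## lagged-path matrices T act on the total (phenotypic) within-person
## factors. Loadings of RI and wave factors onto the observations are
## fixed at 1.

LAG_NAMES <- c("ar_x", "cl_xy", "cl_yx", "ar_y")
RICLPM_BLOCKS <- c("ri", "w1", "i2", "i3")

riclpmBlockParams <- function(block, k, config) {
  inX <- k %in% config$x
  inY <- k %in% config$y
  if (inX && inY) paste0(block, "_", k, "_", c("11", "21", "22"))
  else if (inX) paste0(block, "_", k, "_11")
  else if (inY) paste0(block, "_", k, "_22")
  else character(0)
}

riclpmParamNames <- function(config) {
  comps <- intersect(c("A", "C", "E"), union(config$x, config$y))
  c(unlist(lapply(RICLPM_BLOCKS, function(b)
      unlist(lapply(comps, riclpmBlockParams, block = b, config = config)))),
    paste0(LAG_NAMES, "_1"), paste0(LAG_NAMES, "_2"),
    paste0("mu_", c("x1", "y1", "x2", "y2", "x3", "y3")))
}

## assemble a 2x2 lower-Cholesky block from the full named vector
riclpmBlockMatrix <- function(th, block, k, config) {
  m <- matrix(0, 2, 2)
  pn <- riclpmBlockParams(block, k, config)
  for (p in pn) {
    suf <- sub(".*_", "", p)
    if (suf == "11") m[1, 1] <- th[[p]]
    else if (suf == "21") m[2, 1] <- th[[p]]
    else m[2, 2] <- th[[p]]
  }
  m
}

#' Build a genetically informative RI-CLPM
#'
#' Bivariate three-wave random-intercept cross-lagged panel model with
#' the between-person (random intercept) and within-person (wave-specific)
#' variances decomposed into biometric components. Transmission is
#' phenotypic: the autoregressive/cross-lagged matrix acts on the total
#' within-person factors. Named paths can be fixed at zero via
#' \code{constraints} to form nested models.
#'
#' @param config list with elements \code{x} and \code{y}, each a subset
#'   of \code{c("A","C","E")} containing \code{"E"}; e.g. wellbeing and
#'   negative dependent events are both AE, negative independent events
#'   add C on y.
#' @param traits named character vector \code{c(x = , y = )} of per-twin
#'   measure prefixes, e.g. \code{c(x = "wb", y = "negdep")}.
#' @param constraints character vector of parameter names fixed at zero
#'   (typically lagged paths such as \code{"cl_xy_1"}), or one of the
#'   presets \code{"no_crosslags"}, \code{"no_y_to_x"}, \code{"no_x_to_y"},
#'   \code{"no_autoregressive"}.
#' @return A \linkS4class{SourceLoadingModel} over the 12 observed
#'   variables of a pair.
#' @export
buildRiclpmModel <- function(config = list(x = c("A", "E"), y = c("A", "E")),
                             traits = c(x = "wb", y = "negdep"),
                             constraints = character()) {
  stopifnot(all(c("x", "y") %in% names(config)))
  for (tr in c("x", "y")) {
    if (!"E" %in% config[[tr]])
      stop("every trait must include the E component")
    if (!all(config[[tr]] %in% c("A", "C", "E")))
      stop("components must be a subset of A, C, E")
  }
  constraints <- expandConstraintSet(constraints)
  variables <- as.vector(t(outer(1:3, unname(traits[c("x", "y")]),
                                 function(w, v) paste0(v, w))))
  full <- riclpmParamNames(config)
  unknown <- setdiff(constraints, full)
  if (length(unknown))
    stop("unknown constrained parameter(s): ",
         paste(unknown, collapse = ", "))
  free <- setdiff(full, constraints)
  lower <- rep(-Inf, length(free))
  lower[grepl("^(ri|w1|i2|i3)_._(11|22)$", free)] <- 0
  comps <- intersect(c("A", "C", "E"), union(config$x, config$y))
  I2 <- diag(2)
  Z2 <- matrix(0, 2, 2)
  J <- rbind(I2, I2, I2)
  fullVec <- function(theta) {
    th <- setNames(rep(0, length(full)), full)
    th[free] <- as.numeric(theta)
    th
  }
  loadings <- function(theta) {
    th <- fullVec(theta)
    T1 <- rbind(c(th[["ar_x_1"]], th[["cl_xy_1"]]),
                c(th[["cl_yx_1"]], th[["ar_y_1"]]))
    T2 <- rbind(c(th[["ar_x_2"]], th[["cl_xy_2"]]),
                c(th[["cl_yx_2"]], th[["ar_y_2"]]))
    M1 <- rbind(I2, T1, T2 %*% T1)
    M2 <- rbind(Z2, I2, T2)
    M3 <- rbind(Z2, Z2, I2)
    out <- list()
    for (k in comps) {
      Rk <- riclpmBlockMatrix(th, "ri", k, config)
      S1 <- riclpmBlockMatrix(th, "w1", k, config)
      S2 <- riclpmBlockMatrix(th, "i2", k, config)
      S3 <- riclpmBlockMatrix(th, "i3", k, config)
      out[[k]] <- cbind(J %*% Rk, M1 %*% S1, M2 %*% S2, M3 %*% S3)
    }
    out
  }
  means <- function(theta) {
    th <- fullVec(theta)
    as.numeric(th[paste0("mu_", c("x1", "y1", "x2", "y2", "x3", "y3"))])
  }
  startFun <- function(ds) {
    ind <- individualTable(ds, variables)
    v <- vapply(variables, function(x) var(ind[[x]], na.rm = TRUE), 0)
    m <- vapply(variables, function(x) mean(ind[[x]], na.rm = TRUE), 0)
    vx <- mean(v[c(1, 3, 5)]); vy <- mean(v[c(2, 4, 6)])
    st <- setNames(rep(0, length(full)), full)
    for (k in comps) for (b in RICLPM_BLOCKS) {
      frac <- if (b == "ri") 0.35 else 0.65
      if (k %in% config$x)
        st[paste0(b, "_", k, "_11")] <- sqrt(frac * vx / length(config$x))
      if (k %in% config$y)
        st[paste0(b, "_", k, "_22")] <- sqrt(frac * vy / length(config$y))
    }
    st[paste0("ar_", c("x", "y"), "_1")] <- 0.2
    st[paste0("ar_", c("x", "y"), "_2")] <- 0.2
    st[paste0("mu_", c("x1", "y1", "x2", "y2", "x3", "y3"))] <- m
    st[free]
  }
  new("SourceLoadingModel", name = "riclpm", variables = variables,
      paramNames = free, lower = lower, upper = rep(Inf, length(free)),
      loadings = loadings, means = means, startFun = startFun,
      meta = list(kind = "riclpm", config = config, traits = traits,
                  constraints = constraints, fullNames = full))
}

expandConstraintSet <- function(constraints) {
  presets <- list(
    no_crosslags = c("cl_xy_1", "cl_yx_1", "cl_xy_2", "cl_yx_2"),
    no_y_to_x = c("cl_xy_1", "cl_xy_2"),
    no_x_to_y = c("cl_yx_1", "cl_yx_2"),
    no_autoregressive = c("ar_x_1", "ar_y_1", "ar_x_2", "ar_y_2"))
  unique(unlist(lapply(constraints, function(cn)
    if (cn %in% names(presets)) presets[[cn]] else cn)))
}

#' Structured view of RI-CLPM parameters
#'
#' @param model a RI-CLPM SourceLoadingModel.
#' @param theta free-parameter vector in model order.
#' @return A \linkS4class{RiclpmParams}.
#' @export
riclpmParams <- function(model, theta) {
  stopifnot(model@meta$kind == "riclpm")
  full <- model@meta$fullNames
  th <- setNames(rep(0, length(full)), full)
  th[model@paramNames] <- as.numeric(theta)
  config <- model@meta$config
  comps <- intersect(c("A", "C", "E"), union(config$x, config$y))
  blocks <- lapply(setNames(nm = RICLPM_BLOCKS), function(b)
    lapply(setNames(nm = comps), function(k)
      riclpmBlockMatrix(th, b, k, config)))
  new("RiclpmParams", ri = blocks$ri, w1 = blocks$w1, i2 = blocks$i2,
      i3 = blocks$i3,
      T1 = rbind(c(th[["ar_x_1"]], th[["cl_xy_1"]]),
                 c(th[["cl_yx_1"]], th[["ar_y_1"]])),
      T2 = rbind(c(th[["ar_x_2"]], th[["cl_xy_2"]]),
                 c(th[["cl_yx_2"]], th[["ar_y_2"]])),
      mu = as.numeric(th[paste0("mu_", c("x1", "y1", "x2", "y2",
                                         "x3", "y3"))]),
      config = config)
}

## implied 2x2 covariances of the within-person factors per wave, the
## innovations, and the random intercepts (total and per component)
riclpmCovariances <- function(params) {
  sumTcp <- function(lst) Reduce(`+`, lapply(lst, tcrossprod))
  V1 <- sumTcp(params@w1)
  P2 <- sumTcp(params@i2)
  P3 <- sumTcp(params@i3)
  V2 <- params@T1 %*% V1 %*% t(params@T1) + P2
  V3 <- params@T2 %*% V2 %*% t(params@T2) + P3
  list(ri = sumTcp(params@ri),
       riComp = lapply(params@ri, tcrossprod),
       V = list(V1, V2, V3), psi = list(P2, P3))
}

asRiclpmParams <- function(x) {
  if (is(x, "FitResult")) riclpmParams(x@model, x@theta)
  else { stopifnot(is(x, "RiclpmParams")); x }
}

#' Random-intercept variance shares and their biometric split
#'
#' Per trait and wave, the proportion of total implied variance captured
#' by the random intercept, \eqn{var(RI)/(var(RI)+var(w_w))} (loadings
#' are fixed at 1, so the observed variance is exactly this sum), and the
#' split of the random-intercept variance into its biometric components.
#'
#' @param x a RiclpmParams or a FitResult from an RI-CLPM.
#' @return list with \code{shares} (trait x wave data.frame: riShare,
#'   riVar, withinVar) and \code{riSplit} (per trait and component, the
#'   fraction of RI variance).
#' @export
riVarianceShares <- function(x) {
  params <- asRiclpmParams(x)
  cv <- riclpmCovariances(params)
  traits <- c("x", "y")
  shares <- do.call(rbind, lapply(1:2, function(i)
    do.call(rbind, lapply(1:3, function(w) {
      tot <- cv$ri[i, i] + cv$V[[w]][i, i]
      data.frame(trait = traits[i], wave = w, riVar = cv$ri[i, i],
                 withinVar = cv$V[[w]][i, i],
                 riShare = if (tot > 0) cv$ri[i, i] / tot else NA_real_)
    }))))
  riSplit <- do.call(rbind, lapply(1:2, function(i)
    do.call(rbind, lapply(names(cv$riComp), function(k)
      data.frame(trait = traits[i], component = k,
                 share = if (cv$ri[i, i] > 0)
                   cv$riComp[[k]][i, i] / cv$ri[i, i] else NA_real_)))))
  list(shares = shares, riSplit = riSplit)
}

riclpmPathTable <- function(params) {
  cv <- riclpmCovariances(params)
  sdw <- lapply(cv$V, function(v) sqrt(diag(v)))
  Ts <- list(params@T1, params@T2)
  rows <- list()
  for (tr in 1:2) {
    Vfrom <- sdw[[tr]]; Vto <- sdw[[tr + 1]]
    Tm <- Ts[[tr]]
    for (i in 1:2) for (j in 1:2) {
      raw <- Tm[i, j]
      rows[[length(rows) + 1]] <- data.frame(
        transition = tr, from = c("x", "y")[j], to = c("x", "y")[i],
        param = paste0(if (i == j) paste0("ar_", c("x", "y")[i])
                       else paste0("cl_", c("x", "y")[i], c("x", "y")[j]),
                       "_", tr),
        raw = raw, std = raw * Vfrom[j] / Vto[i])
    }
  }
  do.call(rbind, rows)
}

#' Standardized autoregressive and cross-lagged paths
#'
#' Standardized coefficient = raw path times SD(predictor within-person
#' factor) / SD(outcome within-person factor), using the model-implied
#' factor SDs. Standard errors by the delta method when the fit carries a
#' parameter covariance matrix.
#'
#' @param x a RiclpmParams or FitResult.
#' @param labels optional named trait labels \code{c(x = , y = )} used in
#'   the \code{label} column (defaults to the model's trait prefixes).
#' @return data.frame with one row per lagged path: transition, from, to,
#'   param, raw, std (and stdSE when available), plus a readable label
#'   like \code{"negdep_W1 -> wb_W2"}.
#' @export
standardizePaths <- function(x, labels = NULL) {
  params <- asRiclpmParams(x)
  tab <- riclpmPathTable(params)
  if (is(x, "FitResult")) {
    labels <- labels %||% x@model@meta$traits
    if (nrow(x@vcov) == length(x@theta)) {
      model <- x@model
      th0 <- as.numeric(x@theta)
      ses <- vapply(seq_len(nrow(tab)), function(r) {
        f <- function(th)
          riclpmPathTable(riclpmParams(model, th))$std[r]
        g <- pracma::grad(f, th0)
        sqrt(max(drop(g %*% x@vcov %*% g), 0))
      }, 0)
      tab$stdSE <- ses
    }
  }
  labels <- labels %||% c(x = "x", y = "y")
  tab$label <- sprintf("%s_W%d -> %s_W%d",
                       labels[tab$from], tab$transition,
                       labels[tab$to], tab$transition + 1)
  tab
}

#' Test lagged paths by likelihood-ratio tests against nested models
#'
#' Refits the model with the requested paths fixed at zero and compares
#' to the full fit.
#'
#' @param ds a TwinDataset.
#' @param fullFit a converged FitResult from \code{\link{buildRiclpmModel}}
#'   + \code{\link{fitModel}}.
#' @param which character vector of lagged-path names or a preset (see
#'   \code{\link{buildRiclpmModel}}).
#' @param options optimizer options for the nested refit.
#' @return list with \code{constrained}, \code{lrt} (chisq, df, p) and
#'   \code{nestedFit}.
#' @export
testLaggedPaths <- function(ds, fullFit, which, options = list()) {
  model <- fullFit@model
  stopifnot(model@meta$kind == "riclpm")
  cset <- expandConstraintSet(which)
  nestedModel <- buildRiclpmModel(model@meta$config, model@meta$traits,
                                  constraints = union(model@meta$constraints,
                                                      cset))
  if (is.null(options$start)) {
    st <- fullFit@theta[nestedModel@paramNames]
    options$start <- as.numeric(st)
  }
  nested <- fitModel(nestedModel, ds, options)
  list(constrained = cset, lrt = likelihoodRatioTest(fullFit, nested),
       nestedFit = nested)
}
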