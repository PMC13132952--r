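## Synthetic twin-pair data: simulation from any SourceLoadingModel,
## wave-participation missingness, discretization, and the
## parameter-recovery harness.

## the seven wave-participation patterns and the published counts used as
## default sampling weights (1,132 twins in all three waves; 613/179/78 in
## two; 710/97/70 in one; total 2,879)
PARTICIPATION_PATTERNS <- list(
  `123` = 1:3, `12` = 1:2, `13` = c(1, 3), `23` = 2:3,
  `1` = 1, `2` = 2, `3` = 3)
PARTICIPATION_COUNTS <- c(`123` = 1132, `12` = 613, `13` = 179, `23` = 78,
                          `1` = 710, `2` = 97, `3` = 70)

#' Simulate twin pairs from a source-loading model
#'
#' Draws independent standard-normal sources and maps them through the
#' model's per-twin component loadings. A sources are shared across
#' co-twins with correlation 1 (MZ) or 0.5 (DZ) via source splitting
#' (\eqn{A_t = \sqrt{\bar r}\,z_c + \sqrt{1-\bar r}\,z_t}), C sources are
#' identical for co-twins, E sources independent. Deterministic given the
#' seed.
#'
#' @param model a \linkS4class{SourceLoadingModel}.
#' @param theta generating parameter vector.
#' @param nMZ,nDZ numbers of MZ and DZ pairs.
#' @param seed integer seed.
#' @return A \linkS4class{TwinDataset} of complete continuous pairs.
#' @export
simulatePairs <- function(model, theta, nMZ, nDZ, seed) {
  stopifnot(nMZ >= 0, nDZ >= 0, nMZ + nDZ >= 1)
  if (any(!is.finite(theta))) stop("non-finite generating parameters")
  restore <- withr_seed(seed)
  on.exit(restore())
  lam <- model@loadings(theta)
  mu <- model@means(theta)
  p <- length(model@variables)
  simGroup <- function(n, group) {
    if (n == 0) return(NULL)
    X1 <- matrix(rep(mu, each = n), n, p)
    X2 <- X1
    rbar <- A_SHARE[[group]]
    for (k in names(lam)) {
      L <- lam[[k]]
      s <- ncol(L)
      if (s == 0) next
      if (k == "A") {
        zc <- matrix(rnorm(n * s), n, s)
        z1 <- sqrt(rbar) * zc + sqrt(1 - rbar) * matrix(rnorm(n * s), n, s)
        z2 <- sqrt(rbar) * zc + sqrt(1 - rbar) * matrix(rnorm(n * s), n, s)
      } else if (k == "C") {
        z1 <- z2 <- matrix(rnorm(n * s), n, s)
      } else {
        z1 <- matrix(rnorm(n * s), n, s)
        z2 <- matrix(rnorm(n * s), n, s)
      }
      X1 <- X1 + z1 %*% t(L)
      X2 <- X2 + z2 %*% t(L)
    }
    d <- data.frame(family_id = paste0(group, seq_len(n)),
                    zygosity = group)
    for (j in seq_len(p)) {
      d[[twinCol(model@variables[j], 1)]] <- X1[, j]
      d[[twinCol(model@variables[j], 2)]] <- X2[, j]
    }
    d
  }
  TwinDataset(rbind(simGroup(nMZ, "MZ"), simGroup(nDZ, "DZ")))
}

#' Inject wave-participation missingness (MCAR)
#'
#' Each twin independently draws one of the seven participation patterns
#' \{123, 12, 13, 23, 1, 2, 3\} with the given weights and all measures
#' (and ages) of non-participating waves are blanked. Families where at
#' least one twin retains at least one wave are kept.
#'
#' @param ds a TwinDataset.
#' @param weights named non-negative weights over the seven patterns
#'   (default: the published participation counts).
#' @param seed integer seed.
#' @return A TwinDataset with missingness injected.
#' @export
applyMissingness <- function(ds, weights = PARTICIPATION_COUNTS, seed) {
  if (is.null(names(weights)) ||
      !all(names(weights) %in% names(PARTICIPATION_PATTERNS)))
    stop("weights must be named after the patterns ",
         paste(names(PARTICIPATION_PATTERNS), collapse = ", "))
  if (any(weights < 0) || sum(weights) <= 0)
    stop("degenerate pattern weights")
  restore <- withr_seed(seed)
  on.exit(restore())
  p <- ds@pairs
  n <- nrow(p)
  pat <- matrix(sample(names(weights), 2 * n, replace = TRUE,
                       prob = weights / sum(weights)), n, 2)
  for (t in 1:2) for (w in TWIN_WAVES) {
    drop <- !vapply(pat[, t], function(k)
      w %in% PARTICIPATION_PATTERNS[[k]], TRUE)
    if (!any(drop)) next
    for (m in c(TWIN_MEASURES, "age")) {
      col <- twinCol(paste0(m, w), t)
      if (col %in% names(p)) p[drop, col] <- NA
    }
  }
  meas <- intersect(measureWaveCols(), ds@variables)
  obsCols <- c(twinCol(meas, 1), twinCol(meas, 2))
  keep <- rowSums(!is.na(p[, obsCols, drop = FALSE])) > 0
  TwinDataset(p[keep, , drop = FALSE])
}

#' Discretize continuous simulated scores to instrument scales
#'
#' Wellbeing is affinely rescaled (using each column's empirical mean/SD)
#' to a target mean and SD, then rounded half-up and clamped to 1-10;
#' event counts are rescaled to their target moments, rounded half-up and
#' clamped to [0, category maximum]. Off by default in recovery runs so
#' estimator bias is isolated from coarsening bias.
#'
#' @param ds a TwinDataset of continuous scores.
#' @param rules named list of \code{c(mean, sd)} targets per measure.
#' @return A TwinDataset on the instrument scales.
#' @export
discretizeTwinData <- function(ds,
    rules = list(wb = c(mean = 7.4, sd = 1.6),
                 negdep = c(mean = 2.5, sd = 2.0),
                 negind = c(mean = 1.8, sd = 1.6),
                 posdep = c(mean = 2.2, sd = 1.3))) {
  p <- ds@pairs
  for (m in intersect(names(rules), TWIN_MEASURES)) {
    b <- MEASURE_BOUNDS[[m]]
    tgt <- rules[[m]]
    for (w in TWIN_WAVES) for (t in 1:2) {
      col <- twinCol(paste0(m, w), t)
      if (!col %in% names(p)) next
      v <- p[[col]]
      mu <- mean(v, na.rm = TRUE); s <- sd(v, na.rm = TRUE)
      z <- if (is.finite(s) && s > 0) (v - mu) / s else v - mu
      p[[col]] <- clamp(roundHalfUp(tgt[["mean"]] + tgt[["sd"]] * z),
                        b[1], b[2])
    }
  }
  TwinDataset(p)
}

#' Generating truths for the trivariate wellbeing Cholesky model
#'
#' Standardized generating values: per-wave heritabilities
#' \code{a2 = (0.48, 0.46, 0.26)} with the remainder nonshared
#' environmental, genetic cross-wave correlations (0.8, 0.8, 0.7) and
#' environmental cross-wave correlations (0.25, 0.25, 0.15), chosen so the
#' implied phenotypic stability is about 0.5 between adjacent waves. Total
#' variance 1 and mean 0 per wave on the latent scale.
#'
#' @return list with \code{model} (AE Cholesky), \code{theta} (generating
#'   vector), and \code{targets} (named generating shares).
#' @export
choleskyTruth <- function() {
  a2 <- c(0.48, 0.46, 0.26)
  e2 <- 1 - a2
  corrMat <- function(r12, r23, r13)
    rbind(c(1, r12, r13), c(r12, 1, r23), c(r13, r23, 1))
  A <- outer(sqrt(a2), sqrt(a2)) * corrMat(0.8, 0.8, 0.7)
  E <- outer(sqrt(e2), sqrt(e2)) * corrMat(0.25, 0.25, 0.15)
  model <- buildCholeskyModel("AE")
  a <- lowerChol(A); e <- lowerChol(E)
  ltri <- function(m) m[cbind(c(1, 2, 2, 3, 3, 3), c(1, 1, 2, 1, 2, 3))]
  theta <- setNames(c(ltri(a), ltri(e), rep(0, 3)), model@paramNames)
  list(model = model, theta = theta,
       targets = c(a2_w1 = a2[1], a2_w2 = a2[2], a2_w3 = a2[3],
                   e2_w1 = e2[1], e2_w2 = e2[2], e2_w3 = e2[3]))
}

## split a 2x2 phenotypic covariance block into component blocks: the
## diagonal by the given per-trait component shares, the cross-covariance
## proportionally to the geometric mean of the shares (so every component
## block stays positive semi-definite for moderate cross-correlations; a
## component absent from one trait carries no cross-covariance)
splitBlock <- function(V, shareX, shareY) {
  ks <- union(names(shareX), names(shareY))
  gx <- function(k) shareX[[k]] %||% 0
  gy <- function(k) shareY[[k]] %||% 0
  w <- vapply(ks, function(k) sqrt(gx(k) * gy(k)), 0)
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(ks), length(ks))
  names(w) <- ks
  lapply(setNames(nm = ks), function(k)
    rbind(c(gx(k) * V[1, 1], w[[k]] * V[1, 2]),
          c(w[[k]] * V[2, 1], gy(k) * V[2, 2])))
}

## Cholesky entries of a (possibly structurally degenerate) 2x2 block
blockPathEntries <- function(B, inX, inY) {
  if (inX && inY) {
    L <- lowerChol(B + diag(1e-12, 2))
    c(`11` = L[1, 1], `21` = L[2, 1], `22` = L[2, 2])
  } else if (inX) c(`11` = sqrt(B[1, 1]))
  else c(`22` = sqrt(B[2, 2]))
}

#' Generating truths for the genetic RI-CLPM
#'
#' Constructs raw generating parameters that reproduce, by model algebra,
#' the targeted standardized quantities. For the negative dependent
#' cluster (default): wellbeing random-intercept variance shares 40/40/36
#' percent by wave with an 81/19 A/E split of the intercept variance, and
#' standardized cross-lags NegDep W1 -> WB W2 = -0.11 and
#' WB W2 -> NegDep W3 = -0.10 (with -0.08 and -0.02 for the remaining
#' two). The negative independent variant adds a C component on the event
#' trait and uses its much weaker cross-lags. Quantities the source
#' tables do not determine (event-side intercept share and biometric
#' split, within-person A shares, cross-trait correlations,
#' autoregressive magnitudes) are fixed at values consistent with the
#' reported heritabilities of the event clusters and with moderate
#' within-person stability; see the methods vignette.
#'
#' @param trait \code{"negdep"} or \code{"negind"}.
#' @param stdPaths named standardized lagged paths overriding the
#'   cluster's defaults.
#' @return list with \code{model}, \code{theta}, and \code{targets}
#'   (named generating values of the derived quantities).
#' @export
riclpmTruth <- function(trait = c("negdep", "negind"), stdPaths = NULL) {
  trait <- match.arg(trait)
  stdPaths <- stdPaths %||% switch(trait,
    negdep = c(ar_x_1 = 0.25, cl_xy_1 = -0.11, cl_yx_1 = -0.08,
               ar_y_1 = 0.30, ar_x_2 = 0.25, cl_xy_2 = -0.02,
               cl_yx_2 = -0.10, ar_y_2 = 0.30),
    negind = c(ar_x_1 = 0.25, cl_xy_1 = -0.01, cl_yx_1 = -0.01,
               ar_y_1 = 0.15, ar_x_2 = 0.25, cl_xy_2 = -0.05,
               cl_yx_2 = -0.01, ar_y_2 = 0.15))
  riShareX <- c(0.40, 0.40, 0.36)
  riX <- riShareX[1]                       # wave-1 total fixed at 1
  withinX <- riX * (1 - riShareX) / riShareX
  riY <- if (trait == "negdep") 0.35 else 0.25
  withinY <- rep(if (trait == "negdep") 0.65 else 0.75, 3)
  ## biometric splits: wellbeing RI 81% A; within-person wellbeing A
  ## share chosen so the total wave-1 heritability is ~0.48; event-side
  ## splits follow the reported cluster decompositions (negdep AE with
  ## a2 ~ 0.5; negind ACE with a2 ~ 0.2, c2 ~ 0.4)
  riSplitX <- list(A = 0.81, E = 0.19)
  wShareX <- list(A = 0.26, E = 0.74)
  if (trait == "negdep") {
    config <- list(x = c("A", "E"), y = c("A", "E"))
    riSplitY <- list(A = 0.60, E = 0.40)
    wShareY <- list(A = 0.45, E = 0.55)
  } else {
    config <- list(x = c("A", "E"), y = c("A", "C", "E"))
    riSplitY <- list(A = 0.25, C = 0.40, E = 0.35)
    wShareY <- list(A = 0.20, C = 0.40, E = 0.40)
  }
  ## cross-trait structure: RI correlation -0.3, within-factor -0.2
  riBlock <- rbind(c(riX, -0.3 * sqrt(riX * riY)),
                   c(-0.3 * sqrt(riX * riY), riY))
  Vw <- lapply(1:3, function(w) {
    cxy <- -0.2 * sqrt(withinX[w] * withinY[w])
    rbind(c(withinX[w], cxy), c(cxy, withinY[w]))
  })
  sdx <- sqrt(withinX); sdy <- sqrt(withinY)
  rawT <- function(tr) {
    s <- stdPaths
    rbind(c(s[[paste0("ar_x_", tr)]] * sdx[tr + 1] / sdx[tr],
            s[[paste0("cl_xy_", tr)]] * sdx[tr + 1] / sdy[tr]),
          c(s[[paste0("cl_yx_", tr)]] * sdy[tr + 1] / sdx[tr],
            s[[paste0("ar_y_", tr)]] * sdy[tr + 1] / sdy[tr]))
  }
  T1 <- rawT(1); T2 <- rawT(2)
  P2 <- Vw[[2]] - T1 %*% Vw[[1]] %*% t(T1)
  P3 <- Vw[[3]] - T2 %*% Vw[[2]] %*% t(T2)
  blocks <- list(ri = splitBlock(riBlock, riSplitX, riSplitY),
                 w1 = splitBlock(Vw[[1]], wShareX, wShareY),
                 i2 = splitBlock(P2, wShareX, wShareY),
                 i3 = splitBlock(P3, wShareX, wShareY))
  model <- buildRiclpmModel(config, traits = c(x = "wb", y = trait))
  theta <- setNames(rep(0, length(model@paramNames)), model@paramNames)
  for (b in names(blocks)) for (k in names(blocks[[b]])) {
    entries <- blockPathEntries(blocks[[b]][[k]],
                                k %in% config$x, k %in% config$y)
    theta[paste0(b, "_", k, "_", names(entries))] <- entries
  }
  theta[paste0(LAG_NAMES, "_1")] <- c(T1[1, 1], T1[1, 2], T1[2, 1], T1[2, 2])
  theta[paste0(LAG_NAMES, "_2")] <- c(T2[1, 1], T2[1, 2], T2[2, 1], T2[2, 2])
  theta[grepl("^mu_", names(theta))] <- 0
  list(model = model, theta = theta,
       targets = c(riShare_x_w1 = riShareX[1], riShare_x_w2 = riShareX[2],
                   riShare_x_w3 = riShareX[3], riSplitA_x = riSplitX$A,
                   std_cl_xy_1 = stdPaths[["cl_xy_1"]],
                   std_cl_yx_1 = stdPaths[["cl_yx_1"]],
                   std_cl_xy_2 = stdPaths[["cl_xy_2"]],
                   std_cl_yx_2 = stdPaths[["cl_yx_2"]],
                   std_ar_x_1 = stdPaths[["ar_x_1"]],
                   std_ar_y_1 = stdPaths[["ar_y_1"]],
                   std_ar_x_2 = stdPaths[["ar_x_2"]],
                   std_ar_y_2 = stdPaths[["ar_y_2"]]))
}

#' Define a simulation scenario
#'
#' Bundles a model kind, generating parameters, sample sizes and optional
#' missingness/discretization into a reusable object for
#' \code{\link{simulateScenario}} and \code{\link{recoveryStudy}}. The
#' default sample size approximates the study scale (about 1,100 MZ and
#' 1,780 DZ twins as 550 MZ and 890 DZ pairs).
#'
#' @param kind \code{"cholesky"} or \code{"riclpm"}.
#' @param truth list(model, theta, targets); defaults to
#'   \code{\link{choleskyTruth}()} / \code{\link{riclpmTruth}()}.
#' @param nMZ,nDZ pair counts.
#' @param patternWeights NULL (complete data) or participation-pattern
#'   weights for \code{\link{applyMissingness}}.
#' @param discretize logical; map scores onto the instrument scales.
#' @param seed integer seed.
#' @return list of class \code{"twinScenario"}.
#' @export
simulationScenario <- function(kind = c("cholesky", "riclpm"),
                               truth = NULL, nMZ = 550, nDZ = 890,
                               patternWeights = NULL, discretize = FALSE,
                               seed = 1) {
  kind <- match.arg(kind)
  stopifnot(nMZ + nDZ >= 1)
  truth <- truth %||% switch(kind, cholesky = choleskyTruth(),
                             riclpm = riclpmTruth())
  structure(list(kind = kind, truth = truth, nMZ = nMZ, nDZ = nDZ,
                 patternWeights = patternWeights,
                 discretize = discretize, seed = seed),
            class = "twinScenario")
}

#' Simulate one dataset from a scenario
#'
#' @param scenario a \code{\link{simulationScenario}}.
#' @param seed optional seed override.
#' @return A TwinDataset.
#' @export
simulateScenario <- function(scenario, seed = NULL) {
  seed <- seed %||% scenario$seed
  ds <- simulatePairs(scenario$truth$model, scenario$truth$theta,
                      scenario$nMZ, scenario$nDZ, seed = seed)
  if (scenario$discretize) ds <- discretizeTwinData(ds)
  if (!is.null(scenario$patternWeights))
    ds <- applyMissingness(ds, scenario$patternWeights,
                           seed = deriveSeed(seed, 1))
  ds
}

recoveredQuantities <- function(kind, fit, withSE = FALSE) {
  if (kind == "cholesky") {
    sc <- standardizedComponents(fit)
    out <- c(a2_w1 = sc$a2[1], a2_w2 = sc$a2[2], a2_w3 = sc$a2[3],
             e2_w1 = sc$e2[1], e2_w2 = sc$e2[2], e2_w3 = sc$e2[3])
    ses <- if (withSE && "a2_se" %in% names(sc))
      c(a2_w1 = sc$a2_se[1], a2_w2 = sc$a2_se[2], a2_w3 = sc$a2_se[3],
        e2_w1 = sc$e2_se[1], e2_w2 = sc$e2_se[2], e2_w3 = sc$e2_se[3])
    else NULL
    list(est = out, se = ses)
  } else {
    rv <- riVarianceShares(fit)
    sp <- standardizePaths(fit)
    sh <- rv$shares[rv$shares$trait == "x", ]
    splitA <- rv$riSplit[rv$riSplit$trait == "x" &
                         rv$riSplit$component == "A", "share"]
    std <- setNames(sp$std, paste0("std_", sp$param))
    est <- c(riShare_x_w1 = sh$riShare[1], riShare_x_w2 = sh$riShare[2],
             riShare_x_w3 = sh$riShare[3], riSplitA_x = splitA, std)
    ses <- if (withSE && "stdSE" %in% names(sp))
      setNames(sp$stdSE, paste0("std_", sp$param)) else NULL
    list(est = est, se = ses)
  }
}

#' Parameter-recovery simulation study
#'
#' Simulate-fit-collect loop: replicates are generated from the
#' scenario's generating truth with per-replicate seeds derived from the
#' master seed, refitted, and the derived quantities (standardized
#' variance components for the Cholesky model; random-intercept shares,
#' A split and standardized lagged paths for the RI-CLPM) are summarized
#' as generating value, mean estimate, bias, empirical SD, and (when
#' \code{computeSE}) mean reported SE and nominal 95 percent CI coverage.
#'
#' @param scenario a \code{\link{simulationScenario}}.
#' @param nReplicates number of replicates (at least 2).
#' @param fitOptions optimizer options per replicate (default: single
#'   start from the data-driven heuristic, for throughput).
#' @param computeSE logical; compute per-replicate delta-method SEs and
#'   CI coverage (slower).
#' @return list of class \code{"recoveryReport"}: \code{summary}
#'   data.frame, \code{estimates} matrix, \code{nonconverged} count,
#'   \code{valid} flag (FALSE when more than 20 percent of replicates
#'   failed), \code{seed}.
#' @export
recoveryStudy <- function(scenario, nReplicates, fitOptions = list(),
                          computeSE = FALSE) {
  if (nReplicates < 2) stop("at least 2 replicates are required")
  fitOptions <- modifyList(list(nStarts = 1, gradCheck = FALSE),
                           fitOptions)
  kind <- scenario$kind
  truth <- scenario$truth
  ests <- list(); ses <- list(); bad <- 0L
  for (i in seq_len(nReplicates)) {
    ds <- simulateScenario(scenario, seed = deriveSeed(scenario$seed, i))
    fit <- tryCatch(fitModel(truth$model, ds, fitOptions),
                    error = function(e) NULL)
    if (is.null(fit) || !fit@converged) { bad <- bad + 1L; next }
    if (computeSE) fit <- standardErrors(fit, ds)
    q <- recoveredQuantities(kind, fit, withSE = computeSE)
    ests[[length(ests) + 1]] <- q$est
    ses[[length(ses) + 1]] <- q$se
  }
  if (!length(ests)) stop("no replicate converged")
  E <- do.call(rbind, ests)
  tnames <- intersect(names(truth$targets), colnames(E))
  summary <- data.frame(
    quantity = colnames(E),
    generating = truth$targets[colnames(E)],
    mean = colMeans(E),
    bias = colMeans(E) - as.numeric(truth$targets[colnames(E)]),
    sd = apply(E, 2, sd), row.names = NULL)
  if (computeSE && length(ses) && !is.null(ses[[1]])) {
    S <- do.call(rbind, ses)
    common <- intersect(colnames(E), colnames(S))
    summary$meanSE <- NA_real_
    summary$coverage <- NA_real_
    for (cn in common) {
      idx <- summary$quantity == cn
      gen <- truth$targets[[cn]]
      summary$meanSE[idx] <- mean(S[, cn], na.rm = TRUE)
      if (!is.null(gen) && !is.na(gen)) {
        lo <- E[, cn] - 1.96 * S[, cn]
        hi <- E[, cn] + 1.96 * S[, cn]
        summary$coverage[idx] <- mean(lo <= gen & gen <= hi, na.rm = TRUE)
      }
    }
  }
  structure(list(summary = summary, estimates = E,
                 nReplicates = nReplicates, nonconverged = bad,
                 valid = bad <= 0.2 * nReplicates, seed = scenario$seed,
                 targets = truth$targets[tnames]),
            class = "recoveryReport")
}
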