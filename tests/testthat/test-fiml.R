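test_that("implied moments obey the biometric sharing rules", {
  m <- buildCholeskyModel("AE")
  # identity paths: per-twin block 2I, MZ cross I, DZ cross I/2
  th <- setNames(c(1, 0, 1, 0, 0, 1, 1, 0, 1, 0, 0, 1, 0, 0, 0),
                 m@paramNames)
  mz <- expectedMoments(m, th, "MZ")
  dz <- expectedMoments(m, th, "DZ")
  expect_equal(unname(mz$sigma[1:3, 1:3]), 2 * diag(3))
  expect_equal(unname(mz$sigma[1:3, 4:6]), diag(3))
  expect_equal(unname(dz$sigma[1:3, 4:6]), 0.5 * diag(3))
  expect_equal(unname(mz$mu), rep(0, 6))

  # E-only: cross-twin blocks are zero and MZ = DZ
  thE <- th
  thE[1:6] <- 0
  mzE <- expectedMoments(m, thE, "MZ")
  dzE <- expectedMoments(m, thE, "DZ")
  expect_equal(unname(mzE$sigma[1:3, 4:6]), matrix(0, 3, 3))
  expect_equal(mzE$sigma, dzE$sigma)

  # PSD for random admissible parameter draws
  set.seed(8)
  for (i in 1:25) {
    thr <- runif(15, -1, 1)
    thr[c(1, 3, 6, 7, 9, 12)] <- abs(thr[c(1, 3, 6, 7, 9, 12)])
    for (g in c("MZ", "DZ")) {
      ev <- eigen(expectedMoments(m, thr, g)$sigma, symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gte(min(ev), -1e-10)
    }
  }
  expect_error(expectedMoments(m, replace(th, 1, NaN), "MZ"), "non-finite")
})

test_that("implied moments match the empirical covariance of a large simulation", {
  tr <- choleskyTruth()
  n <- 100000
  ds <- simulatePairs(tr$model, tr$theta, n, 0, seed = 99)
  mom <- expectedMoments(tr$model, tr$theta, "MZ")
  cols <- c(paste0(tr$model@variables, "_t1"),
            paste0(tr$model@variables, "_t2"))
  S <- cov(ds@pairs[, cols]) * (n - 1) / n
  # entrywise within 3 Monte-Carlo standard errors
  for (i in 1:6) for (j in 1:6) {
    mcse <- sqrt((mom$sigma[i, i] * mom$sigma[j, j] + mom$sigma[i, j]^2) / n)
    expect_lt(abs(S[i, j] - mom$sigma[i, j]), 3.5 * mcse)
  }
})

test_that("FIML -2lnL: density identity, row-by-row contract, additivity", {
  uni <- makeUnivariateAEModel()
  # one observed standard-normal value at its mean: -2lnL = log(2*pi)
  d <- data.frame(family_id = "f1", zygosity = "MZ", wb1_t1 = 0,
                  wb1_t2 = NA_real_)
  expect_equal(fimlMinus2LL(uni, c(0, 1, 0), TwinDataset(d)), log(2 * pi),
               tolerance = 1e-12)

  # complete data: equals the closed-form MVN -2lnL via sample moments,
  # and the naive row-by-row evaluation
  m <- buildCholeskyModel("AE")
  tr <- choleskyTruth()
  ds <- simulatePairs(m, tr$theta, 40, 60, seed = 3)
  fast <- fimlMinus2LL(m, tr$theta, ds)
  expect_equal(fast, naiveMinus2LL(m, tr$theta, ds), tolerance = 1e-8)

  # with missingness the pattern-grouped value still matches row-by-row
  dsm <- applyMissingness(ds, seed = 4)
  expect_equal(fimlMinus2LL(m, tr$theta, dsm),
               naiveMinus2LL(m, tr$theta, dsm), tolerance = 1e-8)

  # duplicating every row doubles -2lnL exactly
  p2 <- ds@pairs
  p2$family_id <- paste0(p2$family_id, "_dup")
  dup <- TwinDataset(rbind(ds@pairs, p2))
  expect_equal(fimlMinus2LL(m, tr$theta, dup), 2 * fast, tolerance = 1e-8)
})

test_that("saturated and independence reference fits behave as nested closed forms", {
  tr <- choleskyTruth()
  ds <- simulatePairs(tr$model, tr$theta, 80, 120, seed = 5)
  vars <- tr$model@variables
  sat <- fitSaturated(ds, vars)
  ind <- fitIndependence(ds, vars)

  # closed form at the per-group sample moments
  direct <- 0
  for (g in c("MZ", "DZ")) {
    X <- as.matrix(ds@pairs[ds@pairs$zygosity == g,
                            c(paste0(vars, "_t1"), paste0(vars, "_t2"))])
    n <- nrow(X); k <- ncol(X)
    S <- cov(X) * (n - 1) / n
    direct <- direct +
      n * (k * log(2 * pi) + as.numeric(determinant(S)$modulus) + k)
  }
  expect_equal(sat@minus2LL, direct, tolerance = 1e-8)
  expect_gte(ind@minus2LL, sat@minus2LL)

  # with missing data the optimized saturated fit stays below the model fit
  dsm <- applyMissingness(ds, seed = 6)
  satm <- fitSaturated(dsm, vars)
  fitm <- fitModel(tr$model, dsm, list(nStarts = 1, gradCheck = FALSE))
  expect_lte(satm@minus2LL, fitm@minus2LL + 1e-6)

  # one variable: saturated and independence coincide
  uni <- makeUnivariateAEModel()
  d1 <- TwinDataset(data.frame(family_id = paste0("f", 1:30),
                               zygosity = rep(c("MZ", "DZ"), 15),
                               wb1_t1 = rnorm(30), wb1_t2 = NA_real_))
  expect_equal(fitSaturated(d1, "wb1")@minus2LL,
               fitIndependence(d1, "wb1")@minus2LL, tolerance = 1e-8)
})

test_that("optimization reaches the saturated optimum for a just-identified mean and is a fixed point", {
  tr <- choleskyTruth()
  ds <- simulatePairs(tr$model, tr$theta, 150, 250, seed = 6)
  fit <- fitModel(tr$model, ds, list(nStarts = 2, gradCheck = FALSE))
  expect_true(fit@converged)
  # fitted means equal the implied FIML means; refitting from the
  # optimum does not move the solution
  refit <- fitModel(tr$model, ds, list(nStarts = 1, start = fit@theta,
                                       gradCheck = FALSE))
  expect_equal(refit@minus2LL, fit@minus2LL, tolerance = 1e-6)
  expect_equal(unname(refit@theta), unname(fit@theta), tolerance = 1e-3)
})

test_that("standard errors: closed form for a known-variance mean, invariant to row order", {
  n <- 400
  set.seed(7)
  d <- data.frame(family_id = paste0("f", 1:n),
                  zygosity = rep(c("MZ", "DZ"), n / 2),
                  wb1_t1 = rnorm(n), wb1_t2 = rnorm(n))
  ds <- TwinDataset(d)
  m <- makeKnownVarMeanModel()
  fit <- standardErrors(fitModel(m, ds, list(nStarts = 1)), ds)
  # 2n independent unit-variance observations: SE = 1/sqrt(2n)
  expect_equal(unname(fit@se), 1 / sqrt(2 * n), tolerance = 1e-4)
  expect_true(fit@seReliable)

  perm <- TwinDataset(d[sample(n), ])
  fitp <- standardErrors(fitModel(m, perm, list(nStarts = 1)), perm)
  expect_equal(unname(fitp@se), unname(fit@se), tolerance = 1e-4)
})

test_that("delta-method SE agrees with the profile-likelihood half-width", {
  tr <- choleskyTruth()
  ds <- simulatePairs(tr$model, tr$theta, 800, 1200, seed = 9)
  fit <- standardErrors(fitModel(tr$model, ds,
                                 list(nStarts = 1, gradCheck = FALSE)), ds)
  ci <- profileCI(fit, ds, "a21")
  halfWidth <- (ci[["upper"]] - ci[["lower"]]) / 2
  expect_equal(halfWidth, 1.96 * fit@se[["a21"]], tolerance = 0.2)
})

test_that("fit indices and likelihood-ratio tests follow their definitions", {
  tr <- choleskyTruth()
  ds <- simulatePairs(tr$model, tr$theta, 100, 150, seed = 10)
  vars <- tr$model@variables
  sat <- fitSaturated(ds, vars)
  ind <- fitIndependence(ds, vars)

  # target = saturated: perfect fit
  fi0 <- fitIndices(sat, sat, ind)
  expect_equal(fi0@chisq, 0)
  expect_equal(fi0@cfi, 1)
  expect_equal(fi0@rmsea, NA_real_)  # df = 0

  fit <- fitModel(tr$model, ds, list(nStarts = 1, gradCheck = FALSE))
  fi <- fitIndices(fit, sat, ind)
  expect_equal(fi@df, length(sat@theta) - length(fit@theta))
  expect_equal(fi@aic, fit@minus2LL + 2 * length(fit@theta))
  expect_gte(fi@rmsea, 0)

  # AIC formula audit on a synthetic fit
  stub <- new("FitResult", model = buildCholeskyModel("AE"),
              theta = setNames(rep(0, 10), paste0("p", 1:10)),
              minus2LL = 100, converged = TRUE, gradNorm = NA_real_,
              nPairs = c(MZ = 1, DZ = 1), se = numeric(0),
              vcov = matrix(0, 0, 0), seReliable = NA, details = list())
  expect_equal(AIC(stub), 120)

  # LRT: equal likelihoods -> chisq 0, p 1; 3.84 on 1 df -> p ~ 0.05
  nested <- stub
  nested@theta <- stub@theta[1:9]
  expect_equal(likelihoodRatioTest(stub, nested)$p, 1)
  nested@minus2LL <- 103.8415
  lrt <- likelihoodRatioTest(stub, nested)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p, 0.050, tolerance = 1e-3)
  expect_error(likelihoodRatioTest(nested, stub), "fewer")
})

test_that("fully-missing rows are dropped, leaving AIC comparisons unchanged", {
  tr <- choleskyTruth()
  ds <- simulatePairs(tr$model, tr$theta, 60, 90, seed = 12)
  p <- ds@pairs
  extra <- p[1:5, ]
  extra$family_id <- paste0("empty", 1:5)
  extra[, grep("_t[12]$", names(extra))] <- NA
  ds2 <- TwinDataset(rbind(p, extra))
  expect_equal(fimlMinus2LL(tr$model, tr$theta, ds2),
               fimlMinus2LL(tr$model, tr$theta, ds), tolerance = 1e-10)
})
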